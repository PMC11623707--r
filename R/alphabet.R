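#' Sequence alphabets for k-mer encoding
#'
#' Constructs the alphabet descriptor used throughout the package. Two
#' alphabets are supported: `"nucleotide"` packs each base into 2 bits with
#' the code order A = 00, C = 01, G = 10, T = 11, and `"peptide"` packs each
#' residue into 5 bits covering all 26 letters A-Z (codes 0-25). The 26-letter
#' peptide alphabet deliberately admits the non-canonical letters B, J, O, U,
#' X and Z so that no residue present in an alignment is silently dropped;
#' `*` (stop) is outside the alphabet, so sliding windows containing it are
#' skipped during extraction.
#'
#' Because symbol codes follow the alphabetical order of the symbols and
#' k-mers are packed big-endian (first character in the most significant
#' position), the numeric order of encoded values at fixed k equals the
#' lexicographic order of the k-mer strings.
#'
#' @param kind `"nucleotide"` or `"peptide"`.
#' @return An object of class `kmer_alphabet` with fields `kind`, `symbols`
#'   (ordered character vector) and `bits` (bits per symbol: 2 or 5).
#' @examples
#' kmer_alphabet("nucleotide")$symbols
#' kmer_alphabet("peptide")$bits
#' @export
kmer_alphabet <- function(kind = c("nucleotide", "peptide")) {
  kind <- match.arg(kind)
  if (kind == "nucleotide") {
    symbols <- c("A", "C", "G", "T")
    bits <- 2L
  } else {
    symbols <- LETTERS
    bits <- 5L
  }
  structure(list(kind = kind, symbols = symbols, bits = bits),
            class = "kmer_alphabet")
}

as_alphabet <- function(alphabet) {
  if (inherits(alphabet, "kmer_alphabet")) return(alphabet)
  if (is.character(alphabet) && length(alphabet) == 1L) {
    return(kmer_alphabet(alphabet))
  }
  stop_arg("`alphabet` must be \"nucleotide\", \"peptide\" or a kmer_alphabet object")
}

#' @export
print.kmer_alphabet <- function(x, ...) {
  cat(sprintf("<kmer_alphabet: %s, %d bits/symbol, %d symbols>\n",
              x$kind, x$bits, length(x$symbols)))
  invisible(x)
}

# Supported k ranges per alphabet (capability contract for the width tiers).
kmer_k_range <- function(alphabet) {
  if (alphabet$kind == "nucleotide") c(1L, 63L) else c(3L, 25L)
}

#' Integer width class for a k-mer length
#'
#' Returns the storage tier, in bits, that a packed k-mer code of length `k`
#' falls into. Nucleotide codes (2 bits/base) use the 32-bit class for
#' k <= 15, the 64-bit class for 16 <= k <= 31 and the 128-bit class for
#' 32 <= k <= 63. Peptide codes (5 bits/residue) use 16 bits for k = 3,
#' 32 bits for 4 <= k <= 6, 64 bits for 7 <= k <= 12 and 128 bits for
#' 13 <= k <= 25. The tier is a validated capability contract: k outside the
#' supported range is an error naming the valid range.
#'
#' @param k K-mer length.
#' @param alphabet Alphabet kind or [kmer_alphabet()] object.
#' @return One of 16, 32, 64, 128.
#' @examples
#' width_class(15, "nucleotide") # 32
#' width_class(16, "nucleotide") # 64
#' width_class(3, "peptide")     # 16
#' @export
width_class <- function(k, alphabet = "nucleotide") {
  alphabet <- as_alphabet(alphabet)
  if (length(k) != 1L || is.na(k) || k != as.integer(k)) {
    stop_arg("`k` must be a single integer")
  }
  k <- as.integer(k)
  rng <- kmer_k_range(alphabet)
  if (k < rng[1L] || k > rng[2L]) {
    stop_arg(sprintf("k = %d is outside the supported %s range %d-%d",
                     k, alphabet$kind, rng[1L], rng[2L]))
  }
  if (alphabet$kind == "nucleotide") {
    if (k <= 15L) 32L else if (k <= 31L) 64L else 128L
  } else {
    if (k == 3L) 16L else if (k <= 6L) 32L else if (k <= 12L) 64L else 128L
  }
}
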