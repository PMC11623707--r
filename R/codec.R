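# Compact k-mer codec.
#
# A k-mer is packed big-endian into a bit string: the first character
# occupies the most significant symbol slot, each symbol contributing
# `bits` bits (2 for nucleotide, 5 for peptide). The packed value is carried
# as a fixed-width lowercase hex string so that widths up to 128 bits are
# exact; kmer_value() recovers the numeric value where it fits in a double.
# Fixed-width big-endian packing makes numeric order at fixed k identical to
# the lexicographic order of the k-mer strings.

HEX_CHARS <- c("0", "1", "2", "3", "4", "5", "6", "7",
               "8", "9", "a", "b", "c", "d", "e", "f")

new_kmer_code <- function(hex, k, kind) {
  structure(hex, k = as.integer(k), alphabet = kind, class = "kmer_code")
}

code_hex_width <- function(k, bits) as.integer(ceiling(k * bits / 4))

# symbol-code matrix (k x n, values 0..2^bits-1) -> fixed-width hex strings
pack_codes <- function(mat, bits) {
  k <- nrow(mat)
  n <- ncol(mat)
  nhex <- code_hex_width(k, bits)
  pad <- nhex * 4L - k * bits
  bitm <- matrix(0L, nrow = nhex * 4L, ncol = n)
  for (b in seq_len(bits)) {
    rows <- pad + (seq_len(k) - 1L) * bits + b
    bitm[rows, ] <- (mat %/% 2L^(bits - b)) %% 2L
  }
  nib <- matrix(0L, nrow = nhex, ncol = n)
  for (j in 1:4) {
    nib <- nib + bitm[seq(j, by = 4L, length.out = nhex), , drop = FALSE] * 2L^(4L - j)
  }
  hexmat <- matrix(HEX_CHARS[nib + 1L], nrow = nhex)
  if (nhex == 1L) hexmat[1L, ] else do.call(paste0, lapply(seq_len(nhex), function(r) hexmat[r, ]))
}

# fixed-width hex strings -> symbol-code matrix (k x n)
unpack_codes <- function(hex, k, bits) {
  n <- length(hex)
  nhex <- code_hex_width(k, bits)
  pad <- nhex * 4L - k * bits
  nib <- matrix(match(unlist(strsplit(hex, "", fixed = TRUE)), HEX_CHARS) - 1L,
                nrow = nhex)
  bitm <- matrix(0L, nrow = nhex * 4L, ncol = n)
  for (j in 1:4) {
    bitm[seq(j, by = 4L, length.out = nhex), ] <- (nib %/% 2L^(4L - j)) %% 2L
  }
  mat <- matrix(0L, nrow = k, ncol = n)
  for (b in seq_len(bits)) {
    rows <- pad + (seq_len(k) - 1L) * bits + b
    mat <- mat + bitm[rows, , drop = FALSE] * 2L^(bits - b)
  }
  mat
}

#' Encode k-mers as compact integer codes
#'
#' Packs k-mer strings into big-endian bit representations: 2 bits per
#' nucleotide (A = 00, C = 01, G = 10, T = 11) or 5 bits per amino acid
#' letter (A-Z mapped to 0-25). Input is uppercased first, so soft-masked
#' (lowercase) sequence encodes identically to its unmasked form. All k-mers
#' in one call must share the same length, which must lie in the alphabet's
#' supported range (nucleotide 1-63, peptide 3-25; see [width_class()]).
#'
#' @param kmers Character vector of k-mer strings, all the same length.
#' @param alphabet Alphabet kind or [kmer_alphabet()] object.
#' @return A `kmer_code` vector (one element per input k-mer) carrying the
#'   packed values plus `k` and `alphabet` attributes.
#' @seealso [kmer_decode()], [kmer_value()], [kmer_canonical()]
#' @examples
#' kmer_value(kmer_encode("ACGT")) # 0b00011011 = 27
#' @export
kmer_encode <- function(kmers, alphabet = "nucleotide") {
  alphabet <- as_alphabet(alphabet)
  if (length(kmers) == 0L) {
    return(new_kmer_code(character(0), 0L, alphabet$kind))
  }
  kmers <- toupper(kmers)
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop_arg("all k-mers must have the same length")
  width_class(k, alphabet)  # validates the supported k range
  chars <- unlist(strsplit(kmers, "", fixed = TRUE))
  codes <- match(chars, alphabet$symbols) - 1L
  if (anyNA(codes)) {
    bad <- chars[is.na(codes)][1L]
    stop_with("mafkmer_encoding_error",
              sprintf("character '%s' is not in the %s alphabet", bad, alphabet$kind))
  }
  mat <- matrix(codes, nrow = k)
  new_kmer_code(pack_codes(mat, alphabet$bits), k, alphabet$kind)
}

#' Decode k-mer codes back to strings
#'
#' Inverse of [kmer_encode()]: `kmer_decode(kmer_encode(x))` equals
#' `toupper(x)` for every valid k-mer.
#'
#' @param code A `kmer_code` vector.
#' @return Character vector of uppercase k-mer strings.
#' @export
kmer_decode <- function(code) {
  stopifnot(inherits(code, "kmer_code"))
  if (length(code) == 0L) return(character(0))
  alphabet <- kmer_alphabet(attr(code, "alphabet"))
  k <- attr(code, "k")
  mat <- unpack_codes(unclass(code), k, alphabet$bits)
  sym <- matrix(alphabet$symbols[mat + 1L], nrow = k)
  if (k == 1L) sym[1L, ] else do.call(paste0, lapply(seq_len(k), function(r) sym[r, ]))
}

#' Numeric value of a k-mer code
#'
#' Returns the packed big-endian integer value as a double. Exact only while
#' the packed width fits the 53-bit double mantissa (nucleotide k <= 26,
#' peptide k <= 10); wider codes raise an error — use the hex form
#' (`unclass(code)`) for those.
#'
#' @param code A `kmer_code` vector.
#' @return Numeric vector of code values.
#' @examples
#' kmer_value(kmer_encode(c("A", "C", "G", "T"), "nucleotide")) # 0 1 2 3
#' @export
kmer_value <- function(code) {
  stopifnot(inherits(code, "kmer_code"))
  alphabet <- kmer_alphabet(attr(code, "alphabet"))
  if (attr(code, "k") * alphabet$bits > 52L) {
    stop_arg("code width exceeds exact double precision; use the hex representation")
  }
  vapply(strsplit(unclass(code), "", fixed = TRUE), function(d) {
    Reduce(function(acc, ch) acc * 16 + (match(ch, HEX_CHARS) - 1), d, accumulate = FALSE, init = 0)
  }, numeric(1))
}

#' Reverse complement of nucleotide k-mer codes
#'
#' Operates on the packed representation: symbol codes are reversed and
#' complemented (code -> 3 - code, i.e. A<->T, C<->G). Applying it twice is
#' the identity. Peptide codes have no reverse complement and raise an error.
#'
#' @param code A nucleotide `kmer_code` vector.
#' @return A `kmer_code` vector of the reverse complements.
#' @export
kmer_revcomp <- function(code) {
  stopifnot(inherits(code, "kmer_code"))
  if (attr(code, "alphabet") != "nucleotide") {
    stop_with("mafkmer_unsupported_error",
              "reverse complement is defined only for the nucleotide alphabet")
  }
  if (length(code) == 0L) return(code)
  k <- attr(code, "k")
  mat <- unpack_codes(unclass(code), k, 2L)
  rc <- 3L - mat[rev(seq_len(k)), , drop = FALSE]
  new_kmer_code(pack_codes(rc, 2L), k, "nucleotide")
}

#' Canonical representative of nucleotide k-mer codes
#'
#' Each k-mer is compared with its reverse complement and the
#' lexicographically smaller of the two strings is kept. With the A < C <
#' G < T code order and big-endian packing this coincides with the
#' numerically smaller packed value. Idempotent, and invariant under
#' reverse complement of the input. Peptide codes raise an error.
#'
#' @param code A nucleotide `kmer_code` vector.
#' @return A `kmer_code` vector of canonical representatives.
#' @examples
#' kmer_decode(kmer_canonical(kmer_encode("TTG"))) # "CAA"
#' @export
kmer_canonical <- function(code) {
  rc <- kmer_revcomp(code)
  if (length(code) == 0L) return(code)
  take_rc <- kmer_decode(rc) < kmer_decode(code)
  out <- ifelse(take_rc, unclass(rc), unclass(code))
  new_kmer_code(out, attr(code, "k"), "nucleotide")
}

#' @export
`[.kmer_code` <- function(x, i) {
  new_kmer_code(unclass(x)[i], attr(x, "k"), attr(x, "alphabet"))
}

#' @export
length.kmer_code <- function(x) length(unclass(x))

#' @export
as.character.kmer_code <- function(x, ...) kmer_decode(x)

#' @export
format.kmer_code <- function(x, ...) {
  sprintf("%s [0x%s]", kmer_decode(x), unclass(x))
}

#' @export
print.kmer_code <- function(x, ...) {
  cat(sprintf("<kmer_code: %s, k=%d, n=%d>\n",
              attr(x, "alphabet"), attr(x, "k"), length(x)))
  if (length(x)) print(format(x), quote = FALSE)
  invisible(x)
}
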