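# Per-block k-mer extraction. Blocks are independent alignments: windows
# slide over each record's ungapped sequence and never span records or
# blocks. Within-block counts are pooled per genome into a kmer_group so a
# repeated k-mer costs a single update downstream — alignment blocks are by
# construction highly self-similar, which is what makes this pay off.

#' Remove alignment gaps from an aligned sequence
#'
#' Deletes the gap characters `-` and `.` and uppercases the remainder
#' (soft-masking lowercase is annotation, not sequence identity). For a
#' well-formed MAF record the result's length equals the record's `size`
#' field.
#'
#' @param text Character vector of aligned sequence strings.
#' @return Character vector of ungapped uppercase sequences.
#' @examples
#' ungap("acG-t") # "ACGT"
#' @export
ungap <- function(text) {
  toupper(gsub("[-.]", "", text))
}

# reverse-complement a whole sequence string (pipeline helper; the test
# oracle carries its own independent implementation)
revcomp_string <- function(s) {
  vapply(s, function(x) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", x))))
  }, character(1), USE.NAMES = FALSE)
}

# All valid k-length windows of an ungapped sequence, as uppercase strings
# in positional order. Windows containing a character outside the alphabet
# are skipped; the window still slides by one. With canonical = TRUE each
# window is replaced by the lexicographic minimum of itself and its reverse
# complement.
kmer_windows <- function(sequence, k, alphabet, canonical = FALSE) {
  s <- toupper(sequence)
  L <- nchar(s)
  if (L < k) return(character(0))
  n_win <- L - k + 1L
  win <- substring(s, 1:n_win, k:L)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- cumsum(!(chars %in% alphabet$symbols))
  valid <- (bad[k:L] - c(0L, bad)[1:n_win]) == 0L
  win <- win[valid]
  if (canonical && length(win)) {
    rc_s <- revcomp_string(s)
    rc_win <- rev(substring(rc_s, 1:n_win, k:L))[valid]
    win <- pmin(win, rc_win)
  }
  win
}

#' Extract k-mers from an ungapped sequence
#'
#' Slides a window of length `k` over the sequence and encodes each valid
#' window as a packed k-mer code, in positional order. Windows containing a
#' character outside the alphabet (e.g. `N` for nucleotides, `*` for
#' peptides) are skipped individually; the window still advances by one, so
#' invalid characters never abort extraction. With `canonical = TRUE`
#' (nucleotide only) each emitted code is the canonical representative of
#' the window and its reverse complement.
#'
#' @param sequence A single ungapped sequence string (see [ungap()]).
#' @param k K-mer length.
#' @param alphabet Alphabet kind or [kmer_alphabet()] object.
#' @param canonical Aggregate reverse-complement k-mers? Nucleotide only.
#' @return A `kmer_code` vector with one element per valid window.
#' @examples
#' kmer_decode(extract_kmers("ACNGT", 2)) # "AC" "GT"
#' @export
extract_kmers <- function(sequence, k, alphabet = "nucleotide", canonical = FALSE) {
  alphabet <- as_alphabet(alphabet)
  width_class(k, alphabet)
  if (canonical && alphabet$kind != "nucleotide") {
    stop_with("mafkmer_unsupported_error",
              "canonical aggregation is defined only for the nucleotide alphabet")
  }
  win <- kmer_windows(sequence, k, alphabet, canonical)
  if (!length(win)) return(new_kmer_code(character(0), k, alphabet$kind))
  kmer_encode(win, alphabet)
}

#' Aggregate a block's k-mers into a per-genome count group
#'
#' Extracts k-mers from every record of one alignment block (gaps removed,
#' case folded) and pools them per genome: two records from the same genome
#' in one block contribute to the same entries. Records whose ungapped
#' length is below `k` contribute nothing. The resulting group holds one row
#' per distinct (genome, k-mer) pair with its within-block count, the unit
#' that is merged wholesale into the global store.
#'
#' @param block An `alignment_block` from [read_maf()].
#' @param k K-mer length.
#' @param alphabet Alphabet kind or [kmer_alphabet()] object.
#' @param canonical Aggregate reverse-complement k-mers? Nucleotide only.
#' @param block_index Index of the block in its file (bookkeeping only).
#' @return A `kmer_group`: list with `block_index`, `n_windows` (total valid
#'   windows across records) and `entries`, a data frame with columns
#'   `genome`, `kmer` (decoded string), `code` (packed hex) and `count`.
#' @export
build_kmer_group <- function(block, k, alphabet = "nucleotide",
                             canonical = FALSE, block_index = NA_integer_) {
  alphabet <- as_alphabet(alphabet)
  width_class(k, alphabet)
  if (canonical && alphabet$kind != "nucleotide") {
    stop_with("mafkmer_unsupported_error",
              "canonical aggregation is defined only for the nucleotide alphabet")
  }
  genomes <- genome_of(block$src)
  wins <- lapply(block$text, function(txt) {
    kmer_windows(ungap(txt), k, alphabet, canonical)
  })
  per_genome <- split(wins, genomes)
  rows <- lapply(names(per_genome), function(g) {
    w <- unlist(per_genome[[g]], use.names = FALSE)
    if (!length(w)) return(NULL)
    r <- rle(sort(w, method = "radix"))
    data.frame(genome = g, kmer = r$values,
               count = as.numeric(r$lengths), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  entries <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(genome = character(0), kmer = character(0),
               count = numeric(0), stringsAsFactors = FALSE)
  }
  entries$code <- if (nrow(entries)) {
    unclass(kmer_encode(entries$kmer, alphabet))
  } else {
    character(0)
  }
  structure(
    list(block_index = block_index,
         n_windows = sum(entries$count),
         k = as.integer(k), alphabet = alphabet$kind, canonical = canonical,
         entries = entries[, c("genome", "kmer", "code", "count")]),
    class = "kmer_group")
}
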