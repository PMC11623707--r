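# Synthetic MAF generator and independent counting oracle.
#
# Each block derives all genome records from one random ancestral sequence,
# so sequences within a block are highly similar — exactly the structure
# that motivates block-level k-mer aggregation. The generator returns the
# ungapped record strings as ground truth alongside the MAF text; the
# oracle counts over that ground truth with plain string operations and
# shares no code with the codec, the extractor or the store, so agreement
# between the two routes is a genuine end-to-end check.

#' Specification for a synthetic MAF file
#'
#' Collects the knobs of the generator. Probabilities apply per alignment
#' column (per derived sequence), except `minus_strand_rate`, which applies
#' per record. The ambiguous character is `N` for nucleotide mode and `*`
#' for peptide mode — both fall outside the counting alphabet, so they
#' exercise window skipping. Defaults model a typical multiz-style
#' vertebrate alignment: blocks of 40-120 columns with a few percent of
#' substitutions, gaps and masked bases.
#'
#' @param n_blocks Number of alignment blocks.
#' @param genomes Character vector of genome names (one record per genome
#'   per block).
#' @param block_len_range Integer pair: min/max ancestral columns per block.
#' @param substitution_rate Per-column probability of a substitution.
#' @param gap_rate Per-column probability of a gap (`-`) in one sequence.
#' @param n_rate Per-column probability of the ambiguous character.
#' @param softmask_rate Per-column probability of lowercasing.
#' @param minus_strand_rate Per-record probability of a `-` strand record.
#' @param alphabet `"nucleotide"` or `"peptide"`.
#' @param seed Integer seed; identical specs generate identical bytes.
#' @return A `maf_sim_spec` object.
#' @export
maf_sim_spec <- function(n_blocks = 10,
                         genomes = sprintf("g%02d", 1:4),
                         block_len_range = c(40L, 120L),
                         substitution_rate = 0.05,
                         gap_rate = 0.05,
                         n_rate = 0.01,
                         softmask_rate = 0.05,
                         minus_strand_rate = 0.2,
                         alphabet = c("nucleotide", "peptide"),
                         seed = 1L) {
  alphabet <- match.arg(alphabet)
  probs <- c(substitution_rate, gap_rate, n_rate, softmask_rate, minus_strand_rate)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop_arg("all rates must be probabilities in [0, 1]")
  }
  if (n_blocks < 1 || length(genomes) < 1 || any(!nzchar(genomes))) {
    stop_arg("need at least one block and one named genome")
  }
  if (length(block_len_range) != 2L || block_len_range[1] < 1 ||
      block_len_range[2] < block_len_range[1]) {
    stop_arg("`block_len_range` must be c(min, max) with 1 <= min <= max")
  }
  structure(list(
    n_blocks = as.integer(n_blocks), genomes = genomes,
    block_len_range = as.integer(block_len_range),
    substitution_rate = substitution_rate, gap_rate = gap_rate,
    n_rate = n_rate, softmask_rate = softmask_rate,
    minus_strand_rate = minus_strand_rate,
    alphabet = alphabet, seed = as.integer(seed)
  ), class = "maf_sim_spec")
}

# run expr under a private RNG stream, restoring the caller's stream after
with_sim_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic MAF file with ground truth
#'
#' Emits well-formed MAF text: per block, a random ancestral sequence is
#' mutated independently for every genome (substitutions, gap deletions,
#' ambiguous characters, soft-masking), and each record's size field equals
#' its non-gap character count. Per-genome start offsets accumulate across
#' blocks so coordinates stay plausible. Alongside the text, the per-genome
#' ungapped record strings are returned as ground truth; they are built
#' directly from the simulated characters, independently of the package's
#' own gap handling.
#'
#' @param spec A [maf_sim_spec()].
#' @param path Optional path; when given, the MAF text is written there.
#' @return A list with `lines` (MAF text lines), `truth` (named list:
#'   per genome, the ungapped record strings in block order), `n_blocks`
#'   and `n_records`.
#' @export
generate_maf <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "maf_sim_spec"))
  symbols <- if (spec$alphabet == "nucleotide") {
    c("A", "C", "G", "T")
  } else {
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  }
  ambiguous <- if (spec$alphabet == "nucleotide") "N" else "*"
  genomes <- spec$genomes
  with_sim_seed(spec$seed, {
    lines <- c("##maf version=1 scoring=none",
               "# synthetic alignment produced by mafkmer::generate_maf")
    truth <- stats::setNames(
      replicate(length(genomes), character(0), simplify = FALSE), genomes)
    offsets <- stats::setNames(numeric(length(genomes)), genomes)
    n_records <- 0L
    for (b in seq_len(spec$n_blocks)) {
      L <- sample(spec$block_len_range[1]:spec$block_len_range[2], 1L)
      ancestral <- sample(symbols, L, replace = TRUE)
      lines <- c(lines, sprintf("a score=%d.0", b))
      for (g in genomes) {
        chars <- ancestral
        sub_idx <- stats::runif(L) < spec$substitution_rate
        if (any(sub_idx)) {
          chars[sub_idx] <- vapply(chars[sub_idx], function(ch) {
            sample(setdiff(symbols, ch), 1L)
          }, character(1), USE.NAMES = FALSE)
        }
        amb_idx <- stats::runif(L) < spec$n_rate
        chars[amb_idx] <- ambiguous
        mask_idx <- stats::runif(L) < spec$softmask_rate
        chars[mask_idx] <- tolower(chars[mask_idx])
        gap_idx <- stats::runif(L) < spec$gap_rate
        text_chars <- chars
        text_chars[gap_idx] <- "-"
        ungapped <- chars[!gap_idx]
        size <- length(ungapped)
        strand <- if (stats::runif(1) < spec$minus_strand_rate) "-" else "+"
        src_size <- 10000000
        lines <- c(lines, sprintf("s %s.chr1 %s %d %s %d %s",
                                  g, fmt_count(offsets[[g]]), size, strand,
                                  src_size, paste(text_chars, collapse = "")))
        offsets[[g]] <- offsets[[g]] + size
        truth[[g]] <- c(truth[[g]], paste(ungapped, collapse = ""))
        n_records <- n_records + 1L
      }
      if (stats::runif(1) < 0.2) {
        # annotation line the parser must tolerate
        lines <- c(lines, sprintf("q %s.chr1 %s", genomes[1],
                                  paste(rep("9", L), collapse = "")))
      }
      lines <- c(lines, "")
    }
    if (!is.null(path)) writeLines(lines, path)
    list(lines = lines, truth = truth,
         n_blocks = spec$n_blocks, n_records = n_records)
  })
}

# independent string reverse complement used only by the oracle
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(s, function(x) {
    paste(rev(comp[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Brute-force k-mer counting oracle
#'
#' Counts k-mers over per-genome ungapped record strings with naive string
#' operations only: uppercase, take every length-k substring, drop windows
#' containing any character outside the alphabet, optionally replace each
#' window by the lexicographic minimum of itself and its reverse
#' complement, and tabulate. No packed codes, no partitions, no two-tier
#' store — this is the independent reference that [count_kmers()] must
#' reproduce exactly.
#'
#' @param records Named list: per genome, a character vector of ungapped
#'   sequences (e.g. the `truth` component of [generate_maf()]).
#' @param k K-mer length.
#' @param alphabet `"nucleotide"` or `"peptide"`.
#' @param canonical Aggregate reverse-complement k-mers? Nucleotide only.
#' @return Named list: per genome, a named numeric count vector sorted by
#'   k-mer.
#' @export
oracle_count <- function(records, k, alphabet = "nucleotide", canonical = FALSE) {
  kind <- as_alphabet(alphabet)$kind
  if (canonical && kind != "nucleotide") {
    stop_arg("canonical counting applies to nucleotide sequences only")
  }
  valid_re <- if (kind == "nucleotide") "[^ACGT]" else "[^A-Z]"
  lapply(records, function(seqs) {
    wins <- character(0)
    for (s in seqs) {
      s <- toupper(s)
      L <- nchar(s)
      if (L < k) next
      w <- substring(s, 1:(L - k + 1L), k:L)
      wins <- c(wins, w[!grepl(valid_re, w)])
    }
    if (!length(wins)) return(stats::setNames(numeric(0), character(0)))
    tab <- table(wins)
    counts <- stats::setNames(as.numeric(tab), names(tab))
    if (canonical) {
      u <- names(counts)
      canon <- pmin(u, oracle_revcomp(u))
      agg <- tapply(counts, canon, sum)
      counts <- stats::setNames(as.numeric(agg), names(agg))
    }
    counts[sort(names(counts), method = "radix")]
  })
}
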