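# Shared test helpers: a plain-map reference store (no singleton tier) and
# comparison utilities against the brute-force oracle.

# Reference counter: one explicit count per key, saturating at `cap`.
# Deliberately trivial — the two-tier store must be indistinguishable.
plain_map_store <- function(cap = 4294967295) {
  env <- new.env(parent = emptyenv())
  list(
    add = function(genome_id, code, n = 1) {
      keys <- paste0(genome_id, "|", unclass(code))
      n <- rep_len(as.numeric(n), length(keys))
      for (i in seq_along(keys)) {
        cur <- if (is.null(env[[keys[i]]])) 0 else env[[keys[i]]]
        env[[keys[i]]] <- min(cur + n[i], cap)
      }
    },
    counts = function() {
      keys <- ls(env, sorted = TRUE)
      stats::setNames(vapply(keys, function(k) env[[k]], numeric(1)), keys)
    }
  )
}

partition_effective_counts <- function(partition) {
  df <- effective_counts(partition)
  keys <- paste0(df$genome_id, "|", df$code)
  v <- stats::setNames(df$count, keys)
  v[sort(names(v), method = "radix")]
}

write_sim_maf <- function(sim) {
  path <- withr::local_tempfile(fileext = ".maf", .local_envir = parent.frame())
  writeLines(sim$lines, path)
  path
}

# per-genome tables of a count_result vs. the oracle over the ground truth
expect_matches_oracle <- function(result, truth, k, alphabet = "nucleotide",
                                  canonical = FALSE) {
  oracle <- oracle_count(truth, k, alphabet, canonical)
  expect_setequal(names(result$per_genome), names(oracle))
  for (g in names(oracle)) {
    expect_equal(result$per_genome[[g]], oracle[[g]],
                 info = sprintf("genome %s, k=%d, %s, canonical=%s",
                                g, k, alphabet, canonical))
  }
  invisible(result)
}

# a minimal hand-written MAF for targeted parser/counter tests
tiny_maf_lines <- function() {
  c("##maf version=1",
    "# two blocks, two genomes",
    "a score=1.0",
    "s hg38.chr1 10 8 + 1000 ACGT-ACGT",
    "s mm39.chr5 20 9 - 2000 ACGTTACGT",
    "",
    "a score=2.0",
    "s hg38.chr2 0 4 + 500 AAAA",
    "s mm39.chr5 29 4 + 2000 AAAA",
    "")
}
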