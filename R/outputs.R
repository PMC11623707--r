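# Result writers. Sort orders are fixed (k-mers in C-locale lexicographic
# order; genomes alphabetical within a line) so output bytes are identical
# across runs and across worker counts on the same input.

ensure_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- tryCatch(dir.create(out_dir, recursive = TRUE, showWarnings = FALSE),
                   error = function(e) FALSE)
    if (!isTRUE(ok) && !dir.exists(out_dir)) {
      stop_io(sprintf("cannot create output directory: %s", out_dir))
    }
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop_io(sprintf("output directory is not writable: %s", out_dir))
  }
  invisible(out_dir)
}

fmt_count <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Write one k-mer count file per genome
#'
#' Writes `<genome>.txt` under `out_dir` for every genome in the result,
#' one `<KMER> <COUNT>` line per k-mer, k-mers sorted lexicographically
#' ascending. Singleton k-mers print a count of 1. A genome with no k-mers
#' still gets an (empty) file, so downstream tooling can rely on one file
#' per genome id.
#'
#' @param result A `count_result` from [count_kmers()].
#' @param out_dir Output directory, created if missing.
#' @return Character vector of written file paths, invisibly.
#' @export
write_per_genome <- function(result, out_dir = "results_counter") {
  stopifnot(inherits(result, "count_result"))
  ensure_out_dir(out_dir)
  paths <- character(0)
  for (g in sort(names(result$per_genome), method = "radix")) {
    v <- result$per_genome[[g]]
    path <- file.path(out_dir, paste0(g, ".txt"))
    writeLines(if (length(v)) paste(names(v), fmt_count(v)) else character(0),
               path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write the consolidated single-file output
#'
#' Writes `kmer_counts.txt` under `out_dir`: one line per k-mer present in
#' any genome, grouped first by k-mer and then by genome —
#' `<KMER> <GENOME>:<COUNT>[,<GENOME>:<COUNT>...]`. K-mers are sorted
#' lexicographically, genomes alphabetically within a line; genomes in
#' which a k-mer never occurs are omitted from its line.
#'
#' @param result A `count_result` from [count_kmers()].
#' @param out_dir Output directory, created if missing.
#' @return Path of the written file, invisibly.
#' @export
write_single_file <- function(result, out_dir = "results_counter") {
  stopifnot(inherits(result, "count_result"))
  ensure_out_dir(out_dir)
  genomes <- sort(names(result$per_genome), method = "radix")
  kmer <- unlist(lapply(genomes, function(g) names(result$per_genome[[g]])),
                 use.names = FALSE)
  part <- unlist(lapply(genomes, function(g) {
    v <- result$per_genome[[g]]
    if (length(v)) paste0(g, ":", fmt_count(v)) else character(0)
  }), use.names = FALSE)
  path <- file.path(out_dir, "kmer_counts.txt")
  if (!length(kmer)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ord <- order(kmer, method = "radix")  # stable: genome order preserved within k-mer
  fields <- vapply(split(part[ord], factor(kmer[ord], levels = unique(kmer[ord]))),
                   paste, character(1), collapse = ",")
  writeLines(paste(unique(kmer[ord]), fields), path)
  invisible(path)
}

#' Write the run report
#'
#' Writes `report.txt` under `out_dir`: blocks and records processed, total
#' k-mers emitted, distinct k-mers per genome, the count cap in effect, and
#' every count that saturated at the cap (or an explicit no-overflow line).
#'
#' @param result A `count_result` from [count_kmers()].
#' @param out_dir Output directory, created if missing.
#' @return Path of the written file, invisibly.
#' @export
write_report <- function(result, out_dir = "results_counter") {
  stopifnot(inherits(result, "count_result"))
  ensure_out_dir(out_dir)
  r <- result$report
  lines <- c(
    "mafkmer run report",
    sprintf("k: %d", result$k),
    sprintf("alphabet: %s", result$alphabet),
    sprintf("canonical: %s", if (result$canonical) "yes" else "no"),
    sprintf("alignment blocks processed: %d", r$n_blocks),
    sprintf("sequence records processed: %d", r$n_records),
    sprintf("total k-mers emitted: %s", fmt_count(r$total_kmers)),
    sprintf("count cap: %s", fmt_count(r$count_cap)),
    "distinct k-mers per genome:",
    if (length(r$distinct_per_genome)) {
      sprintf("  %s: %d",
              names(r$distinct_per_genome), r$distinct_per_genome)
    } else {
      "  (no genomes)"
    }
  )
  if (nrow(r$overflows)) {
    lines <- c(lines, "overflowed counts (saturated at cap):",
               sprintf("  %s %s capped at %s", r$overflows$kmer,
                       r$overflows$genome, fmt_count(r$overflows$cap)))
  } else {
    lines <- c(lines, "no overflows: all counts fit within the cap")
  }
  path <- file.path(out_dir, "report.txt")
  writeLines(lines, path)
  invisible(path)
}

#' Read back a consolidated k-mer count file
#'
#' Parses a `kmer_counts.txt` written by [write_single_file()] into the
#' same per-genome shape that [count_kmers()] returns, for round-tripping
#' and cross-format comparison.
#'
#' @param path Path to a single-file output.
#' @return Named list: per genome, a named numeric vector of counts sorted
#'   by k-mer.
#' @export
read_single_file_counts <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  lines <- readLines(path)
  out <- list()
  for (ln in lines) {
    sp <- strsplit(ln, " ", fixed = TRUE)[[1]]
    if (length(sp) != 2L) stop_parse(sprintf("malformed count line: '%s'", ln))
    kmer <- sp[1]
    for (pair in strsplit(sp[2], ",", fixed = TRUE)[[1]]) {
      gc <- strsplit(pair, ":", fixed = TRUE)[[1]]
      if (length(gc) != 2L) stop_parse(sprintf("malformed genome:count pair: '%s'", pair))
      out[[gc[1]]][[kmer]] <- as.numeric(gc[2])
    }
  }
  lapply(out, function(v) {
    v <- unlist(v)
    v[sort(names(v), method = "radix")]
  })
}

#' Read back a per-genome k-mer count file
#'
#' Parses one `<genome>.txt` file written by [write_per_genome()].
#'
#' @param path Path to a per-genome count file.
#' @return Named numeric vector of counts, sorted by k-mer.
#' @export
read_genome_counts <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (!length(lines)) return(stats::setNames(numeric(0), character(0)))
  sp <- strsplit(lines, " ", fixed = TRUE)
  bad <- vapply(sp, length, integer(1)) != 2L
  if (any(bad)) {
    stop_parse(sprintf("malformed count line: '%s'", lines[bad][1]))
  }
  v <- stats::setNames(as.numeric(vapply(sp, `[[`, character(1), 2L)),
                       vapply(sp, `[[`, character(1), 1L))
  v[sort(names(v), method = "radix")]
}
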