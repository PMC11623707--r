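# Global count store.
#
# Genome names map to dense small-integer ids (capacity 256, or 65536 in
# large-genome mode). Counts live in per-merger partitions; a fixed hash of
# the k-mer code routes every occurrence of a given k-mer to the same
# partition, so merging is conflict-free by construction and the union over
# partitions is independent of how many there are.
#
# Each partition is two-tiered: a k-mer seen once for a genome sits in a
# singleton set with no explicit count; on its second occurrence it is
# promoted to the counted map with value two. Most k-mers at large k are
# singletons, so this halves the bookkeeping for the dominant case while
# remaining observationally identical to a plain counting map.

#' Genome-name registry with capacity tiers
#'
#' Creates a registry that assigns dense integer ids `0, 1, 2, ...` to
#' genome names in first-seen order. The default capacity is 256 distinct
#' genomes; `large = TRUE` raises it to 65536 for alignments of unusually
#' many assemblies.
#'
#' @param large Use the 65536-genome capacity tier?
#' @return A `genome_registry` object (environment-backed, mutated in
#'   place by [register_genome()]).
#' @export
genome_registry <- function(large = FALSE) {
  reg <- new.env(parent = emptyenv())
  reg$ids <- new.env(parent = emptyenv())
  reg$names <- character(0)
  reg$capacity <- if (isTRUE(large)) 65536L else 256L
  class(reg) <- "genome_registry"
  reg
}

#' Register a genome name and return its id
#'
#' Idempotent: a name already present returns its existing id; a new name
#' receives the next id. Registration beyond the registry capacity fails
#' with a capacity error telling the user to enable large-genome mode.
#'
#' @param registry A [genome_registry()].
#' @param name Genome name (non-empty string).
#' @return The integer id (0-based).
#' @export
register_genome <- function(registry, name) {
  stopifnot(inherits(registry, "genome_registry"))
  if (length(name) != 1L || is.na(name) || !nzchar(name)) {
    stop_arg("genome `name` must be a non-empty string")
  }
  key <- paste0("g:", name)
  id <- registry$ids[[key]]
  if (!is.null(id)) return(id)
  n <- length(registry$names)
  if (n >= registry$capacity) {
    stop_capacity(sprintf(
      paste0("cannot register genome '%s': the %d-genome capacity is exhausted; ",
             "enable large-genome mode (--large_genome_count) to allow up to 65536"),
      name, registry$capacity))
  }
  id <- n  # ids are 0-based
  registry$ids[[key]] <- id
  registry$names <- c(registry$names, name)
  id
}

#' Names registered in a genome registry, in id order
#' @param registry A [genome_registry()].
#' @return Character vector; element `i` is the name with id `i - 1`.
#' @export
registry_names <- function(registry) {
  stopifnot(inherits(registry, "genome_registry"))
  registry$names
}

#' Two-tier counter partition
#'
#' Creates one partition of the global count store. Keys (genome id, k-mer
#' code) seen exactly once live in a singleton set without an explicit
#' count; on re-occurrence they move to the counted map starting at two.
#' Counts saturate at `count_cap` — they never wrap — and any key that
#' would exceed the cap is recorded for the run report.
#'
#' @param count_cap Maximum representable count: 255, 65535 or 4294967295.
#' @return A `counter_partition` object (environment-backed; [add_count()]
#'   mutates it in place).
#' @export
counter_partition <- function(count_cap = 4294967295) {
  if (!count_cap %in% c(255, 65535, 4294967295)) {
    stop_arg("`count_cap` must be one of 255, 65535, 4294967295")
  }
  p <- new.env(parent = emptyenv())
  p$singletons <- new.env(parent = emptyenv())
  p$counts <- new.env(parent = emptyenv())
  p$overflowed <- new.env(parent = emptyenv())
  p$cap <- count_cap
  class(p) <- "counter_partition"
  p
}

#' Add occurrences of keys to a counter partition
#'
#' Applies the singleton-first update rule per key: an unseen key with
#' `n = 1` enters the singleton set; an unseen key with `n > 1` enters the
#' counted map with `n`; a singleton key is promoted to the counted map
#' with `1 + n`; a counted key is incremented by `n`. Values saturate at
#' the partition's cap and saturating keys are flagged as overflowed.
#' Vectorized over `genome_id`, `code` and `n`.
#'
#' @param partition A [counter_partition()], mutated in place.
#' @param genome_id Integer genome id(s) from [register_genome()].
#' @param code K-mer code hex value(s) (`kmer_code` or plain character).
#' @param n Positive occurrence count(s).
#' @return The partition, invisibly.
#' @export
add_count <- function(partition, genome_id, code, n = 1) {
  stopifnot(inherits(partition, "counter_partition"))
  if (any(n < 1)) stop_arg("`n` must be >= 1")
  keys <- paste0(genome_id, "|", unclass(code))
  n <- rep_len(as.numeric(n), length(keys))
  singles <- partition$singletons
  counts <- partition$counts
  cap <- partition$cap
  for (i in seq_along(keys)) {
    key <- keys[[i]]
    ni <- n[[i]]
    v <- counts[[key]]
    if (!is.null(v)) {
      nv <- v + ni
    } else if (!is.null(singles[[key]])) {
      rm(list = key, envir = singles)
      nv <- 1 + ni
    } else if (ni == 1) {
      singles[[key]] <- TRUE
      next
    } else {
      nv <- ni
    }
    if (nv > cap) {
      nv <- cap
      partition$overflowed[[key]] <- TRUE
    }
    counts[[key]] <- nv
  }
  invisible(partition)
}

#' Effective counts held by a partition
#'
#' Collapses the two tiers into explicit counts: singleton keys report 1,
#' counted keys report their stored value. The optimization is thereby
#' unobservable — this is what a plain counting map would hold.
#'
#' @param partition A [counter_partition()].
#' @return Data frame with columns `genome_id`, `code`, `count`,
#'   `overflowed`.
#' @export
effective_counts <- function(partition) {
  stopifnot(inherits(partition, "counter_partition"))
  skeys <- ls(partition$singletons, sorted = FALSE)
  ckeys <- ls(partition$counts, sorted = FALSE)
  keys <- c(skeys, ckeys)
  counts <- c(rep(1, length(skeys)),
              vapply(ckeys, function(k) partition$counts[[k]], numeric(1),
                     USE.NAMES = FALSE))
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    genome_id = as.integer(vapply(parts, `[[`, character(1), 1L)),
    code = vapply(parts, `[[`, character(1), 2L),
    count = counts,
    overflowed = vapply(keys, function(k) {
      !is.null(partition$overflowed[[k]])
    }, logical(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Deterministic merger assignment for a k-mer code
#'
#' Routes a k-mer code to one of `n_mergers` partitions: a fixed
#' non-cryptographic hash of the code value followed by a modulo. The hash
#' is a base-33 polynomial over the hex digits of the packed value,
#' accumulated modulo 2^31 - 1, so the assignment is a pure function of
#' (value, n_mergers) and reproducible across sessions and platforms.
#' Every occurrence of a given k-mer therefore reaches the same merger,
#' which is what makes concurrent merging conflict-free.
#'
#' @param code K-mer code(s) (`kmer_code` or hex character vector).
#' @param n_mergers Number of partitions (>= 1).
#' @return Integer vector of partition indices in `[0, n_mergers)`.
#' @export
partition_index <- function(code, n_mergers) {
  if (length(n_mergers) != 1L || is.na(n_mergers) || n_mergers < 1) {
    stop_arg("`n_mergers` must be a positive integer")
  }
  hex <- unclass(code)
  if (!length(hex)) return(integer(0))
  nhex <- nchar(hex[[1L]])
  digits <- matrix(match(unlist(strsplit(hex, "", fixed = TRUE)), HEX_CHARS) - 1L,
                   nrow = nhex)
  h <- numeric(length(hex))
  m <- 2147483647  # 2^31 - 1; h * 33 + 17 stays exact in doubles
  for (r in seq_len(nhex)) {
    h <- (h * 33 + digits[r, ] + 1) %% m
  }
  as.integer(h %% n_mergers)
}

#' Merge a block's k-mer group into the partitioned store
#'
#' Routes every (genome, k-mer) entry of the group to its partition via
#' [partition_index()] and applies [add_count()] with the block-level
#' count, so each distinct k-mer in the block costs a single store update.
#' Genomes must already be registered.
#'
#' @param partitions List of [counter_partition()] objects (mutated in
#'   place).
#' @param group A `kmer_group` from [build_kmer_group()].
#' @param registry The [genome_registry()] used for this run.
#' @return The partitions, invisibly.
#' @export
merge_group <- function(partitions, group, registry) {
  stopifnot(inherits(group, "kmer_group"))
  entries <- group$entries
  if (!nrow(entries)) return(invisible(partitions))
  ids <- vapply(entries$genome, function(g) {
    id <- registry$ids[[paste0("g:", g)]]
    if (is.null(id)) {
      stop(sprintf("internal error: genome '%s' not registered before merging", g))
    }
    id
  }, numeric(1), USE.NAMES = FALSE)
  pidx <- partition_index(entries$code, length(partitions))
  for (p in unique(pidx)) {
    sel <- pidx == p
    add_count(partitions[[p + 1L]], ids[sel], entries$code[sel], entries$count[sel])
  }
  invisible(partitions)
}

#' Count k-mers per genome across a MAF file
#'
#' The end-to-end pipeline: parse the MAF into alignment blocks, register
#' genome ids in first-seen order, split the blocks into `n_workers`
#' balanced chunks, aggregate each block into a per-genome k-mer group,
#' and merge the groups into `n_workers` hash-partitioned two-tier count
#' stores. `n_workers` is a parallelism hint shaping the chunk plan and the
#' partition count; because every k-mer is pinned to one partition and
#' per-key additions commute, the result is identical for every
#' `n_workers >= 1`.
#'
#' @param maf Path to a MAF file (plain or gzip).
#' @param k K-mer length (nucleotide 1-63, peptide 3-25).
#' @param alphabet Alphabet kind or [kmer_alphabet()] object.
#' @param canonical Aggregate each k-mer with its reverse complement under
#'   the lexicographically smaller representative? Nucleotide only.
#' @param n_workers Parallelism hint (chunk and partition count).
#' @param large_genomes Allow up to 65536 distinct genomes instead of 256.
#' @param count_cap Count saturation cap: 255, 65535 or 4294967295.
#' @return A `count_result`: list with `per_genome` (named list, one sorted
#'   named count vector per genome) and `report` (totals, distinct k-mers
#'   per genome, cap, overflowed entries).
#' @examples
#' maf <- tempfile(fileext = ".maf")
#' writeLines(c("a", "s g1.chr1 0 8 + 100 ACGTACGT", ""), maf)
#' res <- count_kmers(maf, k = 4)
#' res$per_genome$g1 # ACGT 2, CGTA 1, GTAC 1, TACG 1
#' @export
count_kmers <- function(maf, k, alphabet = "nucleotide", canonical = FALSE,
                        n_workers = 1, large_genomes = FALSE,
                        count_cap = 4294967295) {
  alphabet <- as_alphabet(alphabet)
  width_class(k, alphabet)
  if (canonical && alphabet$kind != "nucleotide") {
    stop_with("mafkmer_unsupported_error",
              "canonical aggregation is defined only for the nucleotide alphabet")
  }
  if (length(n_workers) != 1L || is.na(n_workers) || n_workers < 1) {
    stop_arg("`n_workers` must be a positive integer")
  }
  n_workers <- as.integer(n_workers)
  blocks <- read_maf(maf)

  registry <- genome_registry(large = large_genomes)
  for (b in blocks) {
    for (g in unique(genome_of(b$src))) register_genome(registry, g)
  }

  plan <- chunk_plan(length(blocks), n_workers)
  partitions <- lapply(seq_len(n_workers), function(i) counter_partition(count_cap))
  n_records <- 0L
  total_kmers <- 0
  for (ci in seq_len(nrow(plan))) {
    if (plan$from[ci] > plan$to[ci]) next
    for (bi in plan$from[ci]:plan$to[ci]) {
      group <- build_kmer_group(blocks[[bi]], k, alphabet, canonical,
                                block_index = bi)
      n_records <- n_records + nrow(blocks[[bi]])
      total_kmers <- total_kmers + group$n_windows
      merge_group(partitions, group, registry)
    }
  }

  collected <- do.call(rbind, lapply(partitions, effective_counts))
  genome_names <- registry_names(registry)
  per_genome <- stats::setNames(
    replicate(length(genome_names),
              stats::setNames(numeric(0), character(0)), simplify = FALSE),
    genome_names)
  overflow_rows <- list()
  if (nrow(collected)) {
    codes <- unique(collected$code)
    decoded <- stats::setNames(
      kmer_decode(new_kmer_code(codes, as.integer(k), alphabet$kind)), codes)
    collected$kmer <- decoded[collected$code]
    for (g in unique(collected$genome_id)) {
      sel <- collected$genome_id == g
      v <- stats::setNames(collected$count[sel], collected$kmer[sel])
      per_genome[[genome_names[g + 1L]]] <- v[sort(names(v), method = "radix")]
    }
    osel <- collected$overflowed
    if (any(osel)) {
      overflow_rows <- data.frame(
        genome = genome_names[collected$genome_id[osel] + 1L],
        kmer = collected$kmer[osel],
        cap = count_cap, stringsAsFactors = FALSE)
      overflow_rows <- overflow_rows[order(overflow_rows$genome,
                                           overflow_rows$kmer, method = "radix"), ,
                                     drop = FALSE]
      rownames(overflow_rows) <- NULL
    }
  }
  if (!is.data.frame(overflow_rows)) {
    overflow_rows <- data.frame(genome = character(0), kmer = character(0),
                                cap = numeric(0), stringsAsFactors = FALSE)
  }

  structure(list(
    per_genome = per_genome,
    report = list(
      n_blocks = length(blocks),
      n_records = n_records,
      total_kmers = total_kmers,
      distinct_per_genome = vapply(per_genome, length, integer(1)),
      count_cap = count_cap,
      overflows = overflow_rows
    ),
    k = as.integer(k),
    alphabet = alphabet$kind,
    canonical = canonical
  ), class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<count_result: k=%d %s%s, %d genomes>\n", x$k, x$alphabet,
              if (x$canonical) " (canonical)" else "", length(x$per_genome)))
  cat(sprintf("  blocks: %d  records: %d  k-mers emitted: %s\n",
              r$n_blocks, r$n_records,
              format(r$total_kmers, scientific = FALSE)))
  cat(sprintf("  distinct k-mers: %s\n",
              paste(sprintf("%s=%d", names(r$distinct_per_genome),
                            r$distinct_per_genome), collapse = " ")))
  cat(sprintf("  overflowed entries: %d (cap %s)\n", nrow(r$overflows),
              format(r$count_cap, scientific = FALSE)))
  invisible(x)
}
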