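#' Read alignment blocks from a MAF file
#'
#' Parses a Multiple Alignment Format (MAF) file into a list of alignment
#' blocks. Blocks start at `a` lines; `s` lines carry the aligned sequence
#' records (fields: src, start, size, strand, srcSize, text); `#` comments,
#' `i`/`e`/`q` annotation lines and track lines are tolerated and skipped;
#' a blank line terminates the current block. Gzip-compressed input is
#' detected from the magic bytes. Coordinates are kept as parsed (0-based,
#' ungapped, strand-relative) but only `src`, `strand` and `text` feed the
#' counting pipeline.
#'
#' Malformed `s` lines (wrong field count, non-integer coordinates, a size
#' field that disagrees with the number of non-gap characters, an invalid
#' strand) and `s` lines outside any block raise a parse error naming the
#' offending line number. Records within one block must have equal aligned
#' text length.
#'
#' @param path Path to a MAF file (plain text or gzip).
#' @return A list of `alignment_block` objects; each is a data frame with
#'   columns `src`, `start`, `size`, `strand`, `src_size`, `text`.
#' @examples
#' maf <- tempfile(fileext = ".maf")
#' writeLines(c("##maf version=1", "a", "s hg38.chr1 0 4 + 100 AC-GT",
#'              "s mm39.chr2 5 5 - 200 ACAGT", ""), maf)
#' blocks <- read_maf(maf)
#' length(blocks)          # 1
#' blocks[[1]]$src
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("MAF file not found: %s", path))
  magic <- readBin(path, what = "raw", n = 2L)
  con <- if (length(magic) == 2L && identical(magic, as.raw(c(0x1f, 0x8b)))) {
    gzfile(path, open = "rt")
  } else {
    file(path, open = "rt")
  }
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  parse_maf_lines(lines)
}

parse_maf_lines <- function(lines) {
  blocks <- list()
  cur <- NULL  # list of record lists for the open block
  flush_block <- function() {
    if (is.null(cur) || length(cur) == 0L) return(invisible())
    rec <- data.frame(
      src = vapply(cur, `[[`, character(1), "src"),
      start = vapply(cur, `[[`, numeric(1), "start"),
      size = vapply(cur, `[[`, numeric(1), "size"),
      strand = vapply(cur, `[[`, character(1), "strand"),
      src_size = vapply(cur, `[[`, numeric(1), "src_size"),
      text = vapply(cur, `[[`, character(1), "text"),
      stringsAsFactors = FALSE
    )
    if (length(unique(nchar(rec$text))) > 1L) {
      stop_parse(sprintf(
        "alignment block %d: records have unequal aligned text lengths",
        length(blocks) + 1L))
    }
    class(rec) <- c("alignment_block", "data.frame")
    blocks[[length(blocks) + 1L]] <<- rec
    invisible()
  }
  int_re <- "^[0-9]+$"
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    stripped <- trimws(ln)
    if (!nzchar(stripped)) {
      if (!is.null(cur)) { flush_block(); cur <- NULL }
      next
    }
    c1 <- substr(stripped, 1L, 1L)
    if (c1 == "#") next
    tag_end <- substr(stripped, 2L, 2L)
    if (c1 == "a" && (nchar(stripped) == 1L || tag_end %in% c(" ", "\t"))) {
      flush_block()
      cur <- list()
      next
    }
    if (c1 == "s" && tag_end %in% c(" ", "\t")) {
      if (is.null(cur)) {
        stop_parse(sprintf("line %d: 's' line outside any alignment block", i))
      }
      f <- strsplit(stripped, "[ \t]+")[[1]]
      if (length(f) != 7L) {
        stop_parse(sprintf("line %d: 's' line has %d fields, expected 7",
                           i, length(f)))
      }
      if (!grepl(int_re, f[3]) || !grepl(int_re, f[4]) || !grepl(int_re, f[6])) {
        stop_parse(sprintf("line %d: non-integer coordinate field in 's' line", i))
      }
      if (!f[5] %in% c("+", "-")) {
        stop_parse(sprintf("line %d: strand must be '+' or '-', got '%s'", i, f[5]))
      }
      ungapped_len <- nchar(gsub("[-.]", "", f[7]))
      if (ungapped_len != as.numeric(f[4])) {
        stop_parse(sprintf(
          "line %d: size field %s does not match %d non-gap characters in text",
          i, f[4], ungapped_len))
      }
      cur[[length(cur) + 1L]] <- list(
        src = f[2], start = as.numeric(f[3]), size = as.numeric(f[4]),
        strand = f[5], src_size = as.numeric(f[6]), text = f[7])
      next
    }
    # 'i', 'e', 'q' annotation lines, track/header lines: tolerated, skipped
  }
  flush_block()
  blocks
}

#' Genome name from a MAF src field
#'
#' MAF `src` labels conventionally join an assembly name and a contig name
#' with a dot (e.g. `hg38.chr1`). The genome identifier is taken as the
#' substring before the first dot; a src without any dot is returned
#' unchanged. This prefix rule is a documented convention of this package —
#' the MAF format itself does not mandate one.
#'
#' @param src Character vector of MAF src labels (all non-empty).
#' @return Character vector of genome names.
#' @examples
#' genome_of(c("hg38.chr1", "panTro6.chr2A", "scaffold_12"))
#' @export
genome_of <- function(src) {
  if (length(src) == 0L || any(is.na(src)) || any(!nzchar(src))) {
    stop_arg("`src` must be non-empty")
  }
  sub("\\..*$", "", src)
}

#' Split a block stream into balanced contiguous chunks
#'
#' Assigns `n_blocks` alignment blocks to `n_chunks` contiguous index
#' ranges such that every block lands in exactly one chunk and any two
#' chunks differ in size by at most one block (surplus chunks are empty
#' when `n_chunks > n_blocks`). Chunking is done over parsed block indices,
#' not byte offsets, because the observable contract is about complete
#' blocks.
#'
#' @param n_blocks Number of blocks (>= 0).
#' @param n_chunks Number of chunks (>= 1).
#' @return A `chunk_plan` object: data frame with one row per chunk and
#'   columns `chunk`, `from`, `to`, `size` (`from > to` marks an empty
#'   chunk).
#' @examples
#' chunk_plan(10, 3)$size # 4 3 3
#' @export
chunk_plan <- function(n_blocks, n_chunks) {
  if (length(n_chunks) != 1L || is.na(n_chunks) || n_chunks < 1) {
    stop_arg("`n_chunks` must be a positive integer")
  }
  if (length(n_blocks) != 1L || is.na(n_blocks) || n_blocks < 0) {
    stop_arg("`n_blocks` must be a non-negative integer")
  }
  n_blocks <- as.integer(n_blocks)
  n_chunks <- as.integer(n_chunks)
  base <- n_blocks %/% n_chunks
  extra <- n_blocks %% n_chunks
  sizes <- base + as.integer(seq_len(n_chunks) <= extra)
  to <- cumsum(sizes)
  from <- to - sizes + 1L
  plan <- data.frame(chunk = seq_len(n_chunks), from = from, to = to, size = sizes)
  class(plan) <- c("chunk_plan", "data.frame")
  plan
}
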