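test_that("genome registration is idempotent with first-seen dense ids", {
  reg <- genome_registry()
  expect_equal(register_genome(reg, "hg38"), 0)
  expect_equal(register_genome(reg, "mm39"), 1)
  expect_equal(register_genome(reg, "hg38"), 0)
  expect_equal(registry_names(reg), c("hg38", "mm39"))
})

test_that("capacity tiers hold 256 and 65536 genomes and fail loudly beyond", {
  reg <- genome_registry()
  ids <- vapply(sprintf("g%03d", 1:256), function(n) register_genome(reg, n),
                numeric(1))
  expect_equal(unname(ids), 0:255)
  err <- expect_error(register_genome(reg, "g257"),
                      class = "mafkmer_capacity_error")
  expect_match(conditionMessage(err), "large.genome")

  big <- genome_registry(large = TRUE)
  ids <- vapply(sprintf("g%03d", 1:300), function(n) register_genome(big, n),
                numeric(1))
  expect_equal(unname(ids), 0:299)
})

test_that("two-tier updates follow the singleton-then-two rule", {
  p <- counter_partition()
  code <- unclass(kmer_encode("ACGT"))

  add_count(p, 0, code, 1)
  expect_equal(unname(partition_effective_counts(p)), 1) # singleton, count 1
  expect_length(ls(p$counts), 0L)                        # no explicit count yet

  add_count(p, 0, code, 1)
  expect_equal(unname(partition_effective_counts(p)), 2) # promoted at two
  expect_length(ls(p$singletons), 0L)

  # unseen key arriving with a block-level aggregate n > 1 skips the set
  code2 <- unclass(kmer_encode("TTTT"))
  add_count(p, 0, code2, 5)
  expect_equal(unname(partition_effective_counts(p)), c(2, 5))
  expect_error(add_count(p, 0, code, 0), class = "mafkmer_argument_error")
})

test_that("counts saturate at the cap and flag the overflowed key", {
  p <- counter_partition(count_cap = 255)
  code <- unclass(kmer_encode("AC"))
  add_count(p, 0, code, 254)
  add_count(p, 0, code, 1)   # reaches 255 exactly: no overflow
  df <- effective_counts(p)
  expect_equal(df$count, 255)
  expect_false(df$overflowed)

  add_count(p, 0, code, 1)   # would be 256: saturate and flag
  df <- effective_counts(p)
  expect_equal(df$count, 255)
  expect_true(df$overflowed)
})

test_that("two-tier store is indistinguishable from a plain counting map", {
  withr::local_seed(2024)
  for (cap in c(255, 4294967295)) {
    for (rep in 1:20) {
      p <- counter_partition(count_cap = cap)
      ref <- plain_map_store(cap = cap)
      codes <- unclass(kmer_encode(unique(vapply(1:12, function(i) {
        paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE), collapse = "")
      }, character(1)))))
      for (step in 1:60) {
        gid <- sample(0:2, 1)
        code <- sample(codes, 1)
        n <- sample(c(1, 1, 1, 2, 5, 200), 1)
        add_count(p, gid, code, n)
        ref$add(gid, code, n)
      }
      got <- partition_effective_counts(p)
      want <- ref$counts()
      expect_identical(got, want[sort(names(want), method = "radix")])
    }
  }
})

test_that("partition assignment is deterministic and near-uniform", {
  code <- kmer_encode("ACGTACGTACGTACG")
  expect_equal(partition_index(code, 1), 0L)
  idx <- vapply(1:100, function(i) partition_index(code, 8), integer(1))
  expect_length(unique(idx), 1L)

  withr::local_seed(555)
  kmers <- unique(vapply(1:5000, function(i) {
    paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = "")
  }, character(1)))
  buckets <- partition_index(kmer_encode(kmers), 8)
  expect_true(all(buckets >= 0 & buckets < 8))
  occupancy <- tabulate(buckets + 1L, nbins = 8)
  expect_true(all(occupancy > 0))
  # near-uniform: no bucket further than 25% from the even share
  expect_lt(max(abs(occupancy - length(kmers) / 8)), length(kmers) / 8 * 0.25)
  expect_error(partition_index(code, 0), class = "mafkmer_argument_error")
})

test_that("merging into 1 vs many partitions yields identical unions", {
  spec <- maf_sim_spec(n_blocks = 4, genomes = c("x1", "x2", "x3"), seed = 31)
  sim <- generate_maf(spec)
  blocks <- read_maf(write_sim_maf(sim))
  reg <- genome_registry()
  for (b in blocks) for (g in unique(genome_of(b$src))) register_genome(reg, g)

  union_counts <- function(n_parts) {
    parts <- lapply(seq_len(n_parts), function(i) counter_partition())
    for (i in seq_along(blocks)) {
      merge_group(parts, build_kmer_group(blocks[[i]], 3, block_index = i), reg)
    }
    merged <- do.call(c, lapply(parts, partition_effective_counts))
    merged[sort(names(merged), method = "radix")]
  }
  one <- union_counts(1)
  for (n in c(2, 8)) expect_identical(union_counts(n), one)

  # a given code lands in exactly one partition
  parts <- lapply(1:4, function(i) counter_partition())
  for (i in seq_along(blocks)) {
    merge_group(parts, build_kmer_group(blocks[[i]], 3, block_index = i), reg)
  }
  per_part_codes <- lapply(parts, function(p) {
    unique(effective_counts(p)$code)
  })
  all_codes <- unlist(per_part_codes)
  expect_equal(length(all_codes), length(unique(all_codes)))

  # unregistered genome is an internal error
  empty_reg <- genome_registry()
  expect_error(
    merge_group(list(counter_partition()),
                build_kmer_group(blocks[[1]], 3), empty_reg),
    "not registered")
})

test_that("end-to-end counts reproduce the naive window enumeration", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("a", "s g1.chr1 0 8 + 100 ACGTACGT", ""), path)
  res <- count_kmers(path, k = 4)
  expect_equal(res$per_genome$g1,
               c(ACGT = 2, CGTA = 1, GTAC = 1, TACG = 1))
  expect_equal(res$report$total_kmers, 5)
  expect_equal(res$report$n_blocks, 1L)
  expect_equal(unname(res$report$distinct_per_genome), 4L)
})

test_that("results are invariant in n_workers and symmetric across genomes", {
  spec <- maf_sim_spec(n_blocks = 6, genomes = c("s1", "s2"), seed = 99)
  sim <- generate_maf(spec)
  path <- write_sim_maf(sim)
  base <- count_kmers(path, 5, canonical = TRUE, n_workers = 1)
  for (w in c(2, 8)) {
    expect_identical(count_kmers(path, 5, canonical = TRUE, n_workers = w), base)
  }

  # identical sequences in two genomes give identical tables
  path2 <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("a", "s ga.chr1 0 6 + 100 ACGTGT", "s gb.chr1 0 6 + 100 ACGTGT", ""),
             path2)
  res <- count_kmers(path2, 3)
  expect_identical(res$per_genome$ga, res$per_genome$gb)
})

test_that("per-genome totals conserve the number of valid windows", {
  spec <- maf_sim_spec(n_blocks = 8, genomes = sprintf("g%d", 1:4),
                       n_rate = 0.05, seed = 123)
  sim <- generate_maf(spec)
  res <- count_kmers(write_sim_maf(sim), 4)
  for (g in names(sim$truth)) {
    want <- 0
    for (s in toupper(sim$truth[[g]])) {
      L <- nchar(s)
      if (L < 4) next
      w <- substring(s, 1:(L - 3), 4:L)
      want <- want + sum(!grepl("[^ACGT]", w))
    }
    expect_equal(sum(res$per_genome[[g]]), want)
  }
  expect_equal(res$report$total_kmers,
               sum(vapply(res$per_genome, sum, numeric(1))))
})
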