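random_kmers <- function(n, k, symbols) {
  vapply(seq_len(n), function(i) {
    paste(sample(symbols, k, replace = TRUE), collapse = "")
  }, character(1))
}

test_that("nucleotide bit mapping follows A=00 C=01 G=10 T=11, big-endian", {
  expect_equal(kmer_value(kmer_encode("A")), 0)
  expect_equal(kmer_value(kmer_encode(c("A", "C", "G", "T"))), c(0, 1, 2, 3))
  expect_equal(kmer_value(kmer_encode("ACGT")), 27) # 00 01 10 11
  expect_equal(kmer_value(kmer_encode("AAA")), 0)
  expect_error(kmer_encode("ACN"), "'N'", class = "mafkmer_encoding_error")
})

test_that("decode inverts encode across width tiers and alphabets", {
  withr::local_seed(101)
  nt <- kmer_alphabet("nucleotide")
  for (k in c(1, 3, 15, 16, 31, 32, 63)) {
    kmers <- unique(random_kmers(60, k, nt$symbols))
    expect_identical(kmer_decode(kmer_encode(kmers)), kmers)
  }
  pep <- kmer_alphabet("peptide")
  for (k in c(3, 4, 6, 7, 12, 13, 25)) {
    kmers <- unique(random_kmers(60, k, pep$symbols))
    expect_identical(kmer_decode(kmer_encode(kmers, pep)), kmers)
  }
  # lowercase soft-masked input uppercases before encoding
  expect_identical(kmer_decode(kmer_encode("acgt")), "ACGT")
  expect_identical(kmer_decode(kmer_encode((c("mvk", "WyQ")), pep)), c("MVK", "WYQ"))
})

test_that("encode is strictly monotone in lexicographic order at fixed k", {
  withr::local_seed(77)
  for (k in c(4, 10)) {
    kmers <- sort(unique(random_kmers(100, k, c("A", "C", "G", "T"))), method = "radix")
    vals <- kmer_value(kmer_encode(kmers))
    expect_true(all(diff(vals) > 0))
  }
})

test_that("reverse complement matches the string oracle and is an involution", {
  expect_equal(kmer_decode(kmer_revcomp(kmer_encode("AAC"))), "GTT")
  expect_equal(kmer_decode(kmer_revcomp(kmer_encode("ACGT"))), "ACGT")

  string_rc <- function(s) {
    vapply(strsplit(s, ""), function(ch) {
      paste(rev(c(A = "T", C = "G", G = "C", T = "A")[ch]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  withr::local_seed(42)
  for (k in c(2, 15, 16, 33)) {
    kmers <- random_kmers(50, k, c("A", "C", "G", "T"))
    code <- kmer_encode(kmers)
    rc <- kmer_revcomp(code)
    expect_identical(kmer_decode(rc), string_rc(kmers))
    expect_identical(unclass(kmer_revcomp(rc)), unclass(code))
  }

  pep <- kmer_encode("MVK", "peptide")
  expect_error(kmer_revcomp(pep), class = "mafkmer_unsupported_error")
  expect_error(kmer_canonical(pep), class = "mafkmer_unsupported_error")
})

test_that("canonical selection picks the lexicographically smaller strand", {
  expect_equal(kmer_decode(kmer_canonical(kmer_encode("TTG"))), "CAA")
  expect_equal(kmer_decode(kmer_canonical(kmer_encode("AAC"))), "AAC")
  expect_equal(kmer_decode(kmer_canonical(kmer_encode("AT"))), "AT")

  withr::local_seed(9)
  for (k in c(3, 16, 31)) {
    code <- kmer_encode(random_kmers(60, k, c("A", "C", "G", "T")))
    canon <- kmer_canonical(code)
    # idempotence and reverse-complement symmetry
    expect_identical(unclass(kmer_canonical(canon)), unclass(canon))
    expect_identical(unclass(kmer_canonical(kmer_revcomp(code))), unclass(canon))
    # canonical string is never lexicographically above its reverse complement
    expect_true(all(kmer_decode(canon) <= kmer_decode(kmer_revcomp(canon))))
    # string-level oracle: lexmin(kmer, revcomp)
    expect_identical(kmer_decode(canon),
                     pmin(kmer_decode(code), kmer_decode(kmer_revcomp(code))))
  }
})

test_that("width classes follow the nucleotide 15/31/63 and peptide 3/6/12/25 tiers", {
  nt_expect <- list(`1` = 32, `14` = 32, `15` = 32, `16` = 64, `30` = 64,
                    `31` = 64, `32` = 128, `62` = 128, `63` = 128)
  for (k in names(nt_expect)) {
    expect_equal(width_class(as.integer(k), "nucleotide"), nt_expect[[k]])
  }
  expect_error(width_class(0, "nucleotide"), "1-63", class = "mafkmer_argument_error")
  expect_error(width_class(64, "nucleotide"), "1-63", class = "mafkmer_argument_error")

  pep_expect <- list(`3` = 16, `4` = 32, `5` = 32, `6` = 32, `7` = 64,
                     `11` = 64, `12` = 64, `13` = 128, `24` = 128, `25` = 128)
  for (k in names(pep_expect)) {
    expect_equal(width_class(as.integer(k), "peptide"), pep_expect[[k]])
  }
  expect_error(width_class(2, "peptide"), "3-25", class = "mafkmer_argument_error")
  expect_error(width_class(26, "peptide"), "3-25", class = "mafkmer_argument_error")
})

test_that("kmer_value refuses widths beyond exact double precision", {
  wide <- kmer_encode(paste(rep("A", 27), collapse = ""))
  expect_error(kmer_value(wide), class = "mafkmer_argument_error")
})
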