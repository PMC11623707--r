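---
title: "Counting k-mers in multiple alignment files"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting k-mers in multiple alignment files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mafkmer)
```

## The problem

Comparative genomics and proteomics increasingly start from multiple
sequence alignments stored in the Multiple Alignment Format (MAF): a
line-oriented text format in which each alignment block (`a` line) groups
one aligned record (`s` line) per participating assembly. K-mer counting —
tabulating every length-\(k\) substring of a sequence — is a foundational
step in assembly, sequence comparison and compositional analysis, but the
established counters operate on FASTA-style single-sequence sets. `mafkmer`
counts k-mers *per genome* directly over the alignment blocks of a MAF
file, for nucleotide sequences (2 bits per base) and peptide sequences
(5 bits per residue), without intermediate per-genome FASTA extraction.

The intended users are people comparing k-mer spectra across the genomes of
one alignment: the per-genome tables come out of a single pass over the
file, and the consolidated output lines up each k-mer's counts across
genomes for direct comparison.

## The method

The pipeline has four stages.

**Parsing and chunking.** `read_maf()` parses blocks; `chunk_plan()` splits
the block sequence into `n_workers` contiguous chunks whose sizes differ by
at most one block, so each block belongs to exactly one chunk. Chunking is
defined over parsed block indices rather than byte offsets: the observable
contract is about complete blocks, and byte scanning is a throughput
optimization with no bearing on results.

**Block-level aggregation.** For each block, a sliding window of length
\(k\) runs over every record's *ungapped* sequence (`-` and `.` removed,
case folded). Windows containing a character outside the alphabet (`N`,
`*`, ...) are skipped individually while the window keeps sliding. Because
records within a block are aligned, they are highly similar, so the same
k-mers recur across records; `build_kmer_group()` therefore pools the
block's counts per genome first, and each distinct (genome, k-mer) pair
costs a single update to the global store rather than one per occurrence.

**Canonical aggregation.** With `canonical = TRUE` each k-mer is compared
with its reverse complement and the lexicographically smaller string
represents both. Codes order like strings here: bases are coded
A = 00, C = 01, G = 10, T = 11 and packed big-endian (first character most
significant), so the lexicographic minimum is also the numeric minimum.

**Partitioned two-tier counting.** A fixed hash of the k-mer code, modulo
the number of mergers, pins every occurrence of a k-mer to one partition
(`partition_index()`), which makes merging conflict-free and the union over
partitions independent of the partition count. Within a partition, a
(genome, k-mer) key seen once sits in a *singleton set* with no stored
count; a second occurrence promotes it to the counted map starting at two
(`add_count()`). At larger \(k\) most k-mers per genome are singletons, so
the dominant case stores no count at all, while effective counts are
provably identical to a plain counting map — a transparency the test suite
checks by fuzzing both stores side by side.

## A worked example

```{r example}
maf <- system.file("extdata", "synthetic_example.maf", package = "mafkmer")
res <- count_kmers(maf, k = 15, canonical = TRUE, n_workers = 4)
res
head(res$per_genome$hg38, 3)
```

Each per-genome table maps decoded k-mers to counts; `write_per_genome()`
emits them as `<KMER> <COUNT>` files, and `write_single_file()` writes the
consolidated `<KMER> <GENOME>:<COUNT>,...` table grouped by k-mer.

## Parameters that matter

- `k` — k-mer length. Supported ranges follow the packed-integer width
  tiers: nucleotide 1–63 (32-bit class up to k = 15, 64-bit to k = 31,
  128-bit to k = 63) and peptide 3–25 (16-bit at k = 3, 32-bit to k = 6,
  64-bit to k = 12, 128-bit to k = 25). The tiers are enforced as the
  supported-k contract; storage itself uses fixed-width hex strings so that
  128-bit codes stay exact in R, which has no native integer wider than
  53 usable bits.
- `canonical` — aggregate each k-mer with its reverse complement
  (nucleotide only). Use it when strand is not meaningful, e.g. whole-genome
  composition.
- `n_workers` — a parallelism hint: it sets the chunk plan and the number of
  count partitions. Results are bit-identical for every value; the package
  deliberately implements the *contract* of the producer–consumer design
  (disjoint chunks of complete blocks; k-mers pinned to one merger;
  commuting per-key additions) with a serial scheduler, since correctness,
  not throughput, is the testable surface in R.
- `count_cap` — maximum representable count (255, 65535 or the default
  4294967295). Counts saturate at the cap — they never wrap — and every
  saturated entry is listed in the run report.
- `large_genomes` — raises the genome-id capacity from 256 to 65536.
  Registration past capacity fails with an error naming the flag.

## Conventions the MAF format leaves open

Several behaviors are conventions fixed by this package, documented here
because the format (and common practice) underdetermines them:

- **Genome identifiers** are the `src` prefix before the first dot
  (`hg38.chr1` → `hg38`); a dot-free `src` is used whole.
- **Gaps** `-` and `.` are deleted before windowing; the window continues
  across former gap positions, because k-mers are substrings of the source
  sequence and gaps are alignment artifacts.
- **Soft-masked lowercase** is uppercased: masking is annotation, not
  sequence identity.
- **Minus-strand records** are counted from the text exactly as stored
  (MAF stores the reverse-complemented sequence for `-` strand); no extra
  re-complementation is applied — canonical mode exists precisely to unify
  strands when that is wanted.
- **The peptide alphabet** is all 26 letters, not the 20 canonical amino
  acids: 5 bits admit 32 symbols, and accepting B, J, O, U, X, Z avoids
  silently dropping annotated residues. `*` (stop) is outside the alphabet,
  so windows containing it are skipped.
- **Output ordering** is fixed (k-mers in C-locale lexicographic order,
  genomes alphabetical within a line) so outputs are byte-reproducible.
- **The partition hash** is a base-33 polynomial over the hex digits of the
  packed code value, accumulated modulo \(2^{31}-1\) — values that stay
  exact in double arithmetic — then reduced modulo the merger count. Any
  fixed mixer would do; this one is simple, portable and documented.

## The synthetic generator and what passing tests show

`generate_maf()` builds each block from one random ancestral sequence and
mutates it per genome (substitutions, gap deletions, ambiguous characters,
soft-masking, minus-strand records), so intra-block similarity is high —
exactly the structure that motivates block-level aggregation. Defaults
model a multiz-style vertebrate alignment: blocks of 40–120 columns, 5%
substitutions, 5% gaps, 1% ambiguous characters, 5% soft-masking, 20%
minus-strand records. The generator returns the ungapped record strings as
ground truth, built directly from the simulated characters so the oracle
shares no code with the parser or extractor.

`oracle_count()` is the independent reference: plain string windows,
regex-based validity, string reverse complements, `table()` tabulation —
no codecs, partitions or tiers. The central acceptance property is exact
agreement between `count_kmers()` and this oracle over a hundred seeded
alignments spanning 1–50 blocks, 1–20 genomes, both alphabets, every width
tier and both canonical settings, with worker counts varied.

What that does *not* show: the generator produces uniform substitution and
gap processes with single-column indels and no rate heterogeneity, repeat
structure or genuine phylogeny, and its files are small. Agreement on it
validates the counting semantics, not performance or robustness to the
full diversity of real multiz output (e.g. `e`-line-only blocks or
duplicated-species rows are tolerated structurally but not modeled by the
generator).

## Numerical and degenerate-input choices

- Counts are doubles internally (exact through \(2^{53}\), far beyond the
  largest cap) and printed in fixed notation.
- A record whose ungapped length is below `k` contributes nothing; a
  genome with no k-mers still appears with an empty table and an empty
  per-genome file, so one-file-per-genome is a reliable contract.
- An all-gap record ungaps to the empty string and is handled by the same
  rule.
- Empty chunks (more workers than blocks) are legal and inert.
- Ties in canonical selection (palindromes) keep the forward k-mer; both
  strands decode identically so the choice is unobservable.
- Problem sizes in the shipped tests — up to 50 blocks and 20 genomes per
  synthetic file, 100 files in the central property — were chosen to
  exercise every tier and flag combination at sizes where the brute-force
  oracle itself remains trustworthy and quick.

## Limitations

- Throughput: the implementation is vectorized R with a serial scheduler;
  it validates the algorithm's semantics and is comfortable at the scale of
  test alignments, but it is not a drop-in replacement for a compiled
  multithreaded counter on multi-gigabyte alignments.
- No indexed or streaming MAF access: files are parsed whole.
- No IUPAC degenerate-code expansion: any character outside the strict
  alphabet skips its windows.
- K-mers never span record or block boundaries by design — blocks are
  independent alignments.
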