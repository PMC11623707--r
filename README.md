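# mafkmer

K-mer counting in Multiple Alignment Format (MAF) files.

Multiple sequence alignments — the starting point of comparative genomics
and proteomics — are commonly stored as MAF: blocks of aligned records, one
record per assembly. Established k-mer counters operate on FASTA-style
sequence sets; `mafkmer` counts k-mers **per genome directly over the
alignment blocks**, for nucleotide and peptide sequences, so per-genome
k-mer spectra and cross-genome comparisons come out of a single pass over
the alignment.

## The method

For a k-mer length *k*:

1. **Parse and chunk.** Blocks are parsed from the MAF (`read_maf()`) and
   split into contiguous chunks of complete blocks differing in size by at
   most one (`chunk_plan()`).
2. **Aggregate per block.** A sliding window of length *k* runs over every
   record's ungapped sequence; windows containing out-of-alphabet
   characters (e.g. `N`) are skipped individually. Because aligned records
   are highly similar, counts are pooled per genome *within* the block
   first (`build_kmer_group()`), so each distinct (genome, k-mer) pair
   costs one global update instead of one per occurrence.
3. **Encode.** K-mers are packed big-endian into compact codes — 2
   bits/base (A=00, C=01, G=10, T=11; 32/64/128-bit classes for k ≤ 15 /
   ≤ 31 / ≤ 63) or 5 bits/residue (16/32/64/128-bit classes for k = 3 /
   ≤ 6 / ≤ 12 / ≤ 25). With `canonical = TRUE` each k-mer is aggregated
   with its reverse complement under the lexicographically smaller of the
   two, which under this packing is also the numerically smaller code.
4. **Count in a partitioned two-tier store.** A fixed hash of the code,
   modulo the merger count, pins every occurrence of a k-mer to one
   partition, making merges conflict-free and the result independent of
   the worker count. Within a partition, a key seen once sits in a
   singleton set without a stored count; a second occurrence promotes it
   to the counted map starting at two. Counts saturate at a configurable
   cap (255 / 65535 / 4294967295) and saturated entries are listed in the
   run report.

Genome identifiers (the `src` prefix before the first dot, `hg38.chr1` →
`hg38`) map to dense ids with a 256-genome capacity, or 65536 with
`large_genomes = TRUE`.

## Worked example

```r
library(mafkmer)
maf <- system.file("extdata", "synthetic_example.maf", package = "mafkmer")
res <- count_kmers(maf, k = 15, canonical = TRUE, n_workers = 4)
res
#> <count_result: k=15 nucleotide (canonical), 4 genomes>
#>   blocks: 8  records: 32  k-mers emitted: 1738
#>   distinct k-mers: hg38=427 panTro6=486 mm39=374 rn7=451
#>   overflowed entries: 0 (cap 4294967295)
head(res$per_genome$hg38, 3)
#> AAAAAACCGCTACCC AAAAACCGCTACCCA AAAACCGCTACCCAA
#>               1               1               1
```

The bundled alignment is synthetic (produced by `generate_maf()`, 8 blocks
of 4 genomes). 1738 valid 15-mer windows were found across the 32 records;
after canonical aggregation, hg38 contributes 427 distinct 15-mers, each
shown with its occurrence count. `write_per_genome(res)` writes one
`<genome>.txt` of `<KMER> <COUNT>` lines per genome;
`write_single_file(res)` writes the consolidated table:

```
AAAAAACCGCTACCC hg38:1
AAAAACCGCTACCCA hg38:1
AAAACAGACCCTTCC panTro6:1
```

## Command line

The same pipeline is installed as `exec/maf_counter`
(positional order: k, input MAF, threads):

```sh
maf_counter -c -s 15 input.maf 16     # canonical 15-mers, single-file output
maf_counter -c 15 input.maf 16        # one file per genome
```

Flags: `-c` canonical, `-s`/`--single_file_output`, `--amino` (peptide),
`--large_genome_count`, `--max_kmer_count {8|16|32}`, `--out_dir DIR`.
Outputs land in `results_counter/` by default, alongside a `report.txt`
listing totals and any counts that saturated the cap.

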