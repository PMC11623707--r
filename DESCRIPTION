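Package: mafkmer
Title: K-Mer Counting in Multiple Alignment Format (MAF) Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Counts k-mer occurrences per genome across the alignment blocks
    of Multiple Alignment Format (MAF) files, for nucleotide and peptide
    alphabets. K-mers are packed into compact big-endian integer codes (2
    bits per nucleotide, 5 bits per amino acid), optionally aggregated with
    their reverse complements under the canonical (lexicographically
    smaller) representative, accumulated per alignment block, and merged
    into a two-tier count store that keeps first occurrences in a singleton
    set before promoting repeated k-mers to an explicit counted map. Results
    are written either as one file per genome or as a consolidated
    k-mer-by-genome table, together with a run report. A seeded synthetic
    alignment generator and an independent brute-force counting oracle are
    included for validation, plus a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
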