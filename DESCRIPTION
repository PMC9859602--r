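Package: satkit
Title: Satellitome Quantification from Short Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying satellite DNA (satDNA) families from
    low-coverage short-read data. Simulates genomes carrying tandem satDNA
    arrays with controlled abundance and divergence, detects monomer
    periodicity in tandem-repetitive contigs, aligns reads to dimer or
    concatemer references with a seeded Smith-Waterman strategy, and
    computes the standard satellitome statistics: per-family genome
    proportion, Kimura 2-parameter divergence landscapes, tandem structure
    index (TSI), divergence peak (DivPeak) and relative peak size (RSP),
    plus cross-sample comparisons (log2 abundance ratios, presence calls,
    Spearman rank correlation and the exact Wilcoxon signed-rank test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
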