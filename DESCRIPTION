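Package: ppredit
Title: Design and Off-Target Analysis of Synthetic PPR RNA Editing Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing PLS-class pentatricopeptide repeat (PPR)
    C-to-U RNA editing factors from position-specific consensus motifs,
    predicting their RNA binding with configurable PPR-code scoring tables,
    scanning genomes for candidate binding/editing sites, and detecting
    editing and off-target events from strand-specific RNA-seq nucleotide
    counts using Fisher exact tests with Hochberg step-up correction and
    pseudocounted odds ratios. Includes a synthetic-data generator that
    produces chloroplast-like genomes, strand-specific base-count tables and
    SAM read sets with recorded ground truth, and a configurable end-to-end
    off-target analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    rtracklayer,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
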