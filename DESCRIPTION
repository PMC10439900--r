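Package: mreseq
Title: Methylation-Sensitive Restriction Enzyme Sequencing Analysis of
    Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for methylation-sensitive restriction enzyme
    sequencing (MRE-Seq) of cell-free DNA: enumeration of SacII (CCGCGG)
    recognition sites in a reference genome, simulation of cfDNA libraries
    with class-specific demethylation and tumor-fraction mixing, read QC and
    directional UMI deduplication, trimmed-mean depth normalization, a
    feed-forward neural network cancer-score model trained under repeated
    nested cross-validation, sensitivity evaluation at anchored specificity
    with Wilson confidence intervals, a two-stage cancer-signal-origin
    cascade, and marker/confounder diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    rtracklayer,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
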