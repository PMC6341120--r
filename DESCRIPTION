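Package: sccage
Title: Single-Cell 5' CAGE Simulation, Tag Processing, and Enhancer
    Directionality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-cell cap analysis of gene expression (CAGE)
    data: a ground-truth synthetic-data generator for stranded paired
    5'-tag experiments (bursty promoter expression, allele-resolved
    enhancer RNA transcription, ERCC-style spike-in capture,
    strand-invasion artifacts, fluorescence color-coded multiplexing);
    tag-level processing (coordinate duplicate collapse, upstream-linker
    strand-invader flagging, masking, strand-resolved 5'-end counting);
    fluorescence-based timepoint demultiplexing; spike-in performance
    metrics (quantification accuracy, logistic molecular detection limit,
    first-base fraction, mix fold-change recovery); cell and feature
    quality control, normalization, batch detrending and high-variance
    feature selection; and enhancer bidirectionality, downsampling and
    Gini burstiness analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    limma,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
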