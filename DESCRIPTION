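Package: centroscan
Title: Telomere-to-Telomere Assembly QC, Centromere Prediction and
    Centromeric Retrotransposon Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the bespoke computations used to
    finish and validate a fungal telomere-to-telomere genome assembly:
    telomeric-repeat detection and read-based telomere patching, canonical
    k-mer consensus-accuracy (QV) arithmetic, binned coverage-anomaly and
    MQ0-dominance flagging, blast-coverage rDNA copy-number estimation,
    Hi-C observed/expected centromere prediction fused with sequence-feature
    tracks, Levan arm-ratio chromosome classification, and structural
    annotation of centromeric Copia LTR retrotransposons (paired versus solo
    elements, TSR/PBS/PPT and GAG-INT-RT-RH order). Includes a deterministic
    synthetic-genome generator that emulates the statistical structure the
    analyses assume and records the planted ground truth for every feature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    grid,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    stats,
    utils,
    methods,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
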