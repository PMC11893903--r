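Package: rloopscreen
Title: Scoring and Spike-In Calibration for DNA:RNA Hybrid Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying DNA:RNA hybrid (R-loop) phenotypes in
    systematic yeast screens and genomics assays. Implements percentile-based
    recombination indices and Mann-Whitney ranking for flow-cytometry
    reporter screens, Fisher-exact scoring of replica-pinning colony arrays,
    dot-blot serial-dilution hybrid quantification, spike-in calibrated
    strand-specific DRIP-seq densities (occupancy-ratio normalization,
    template/non-template gene densities, TSS-TES metagene matrices, RNase H
    sensitivity), OK-seq slope-based co-directional/head-on gene orientation
    calls, DRIP-qPCR adjusted percent-of-input, and nucleus segmentation with
    local-maxima focus counting for repair-foci imaging. A seeded synthetic
    data generator emits every input with known ground truth so that each
    scoring stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite,
    tiff,
    EBImage,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
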