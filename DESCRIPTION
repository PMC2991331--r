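Package: ladscape
Title: Lamina-Associated Domain Calling and Insulator Peak Analysis for DamID Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of DamID tiling-microarray tracks of
    nuclear-lamina interaction and insulator-protein binding in Drosophila.
    Implements loess normalization and dye-swap averaging of probe-level
    log2(Dam-fusion/Dam-only) tracks, lamina-associated domain (LAD) calling
    with a sliding edge filter, insulator binding-peak calling via a
    running-mean derivative with empirical-Bayes moderated per-probe
    significance and FDR control, mirrored border-alignment meta-profiles,
    permutation-based interval enrichment statistics, relative-score position
    weight matrix scanning, differential nuclear-lamina interaction analysis
    after perturbation, and a ground-truth synthetic DamID data generator.
    All user-facing functions take and return tidy data frames.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    BiocGenerics,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
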