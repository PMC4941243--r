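Package: alffnet
Title: Pathway Imaging Genetics of Low-Frequency BOLD Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for pathway-based imaging genetics of
    resting-state fMRI. Computes voxelwise amplitude of low-frequency
    fluctuations (ALFF, 0.01-0.08 Hz) from 4D BOLD series, maps
    SNP-by-diagnosis interactions with a covariate-adjusted general linear
    model, controls family-wise error with Monte-Carlo (AlphaSim-style)
    cluster-extent thresholds and a two-stage within-gene/between-gene
    Bonferroni ledger, and reconstructs ROI functional-connectivity networks
    with Fisher-z edge weights, node strength, edge-wise group tests and
    brain-behaviour correlations. Includes genotype quality control
    (Hardy-Weinberg tests, minor-allele-frequency filters, genetic-model
    selection) and a synthetic-data generator with known ground truth so the
    whole pipeline is testable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
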