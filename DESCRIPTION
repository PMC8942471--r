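Package: lipidcohort
Title: QC-Anchored Harmonization and Association Analysis for Longitudinal
    Cohort Lipidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end computational chain for targeted LC-MS lipidomics in
    longitudinal birth cohorts: pooled-QC median-centring batch harmonization
    with biological-sample variance rescaling, below-detection zero
    replacement, k-nearest-neighbour imputation, dual-criterion (summed
    Z-score and principal-component distance) sample outlier detection,
    per-lipid covariate-adjusted linear-model association testing with
    percentage-change reporting and per-term Benjamini-Hochberg adjustment,
    paired fold-change comparisons across time points, and dynamic-time-
    warping trajectory clustering with partitioning around medoids. Includes
    a seeded synthetic cohort generator emulating the multi-batch QC design
    so every stage is testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
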