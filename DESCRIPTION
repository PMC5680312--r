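Package: dsharenet
Title: Discordancy Partitioning for Cross-Study Penalized Regression
Version: 0.1.0
Authors@R:
    person("Maren", "Keller", email = "maren.keller@example.org",
           role = c("aut", "cre"))
Description: Joint modelling of two drug-sensitivity cohorts with shared
    coefficients and dataset-specific discrepancy coefficients, estimated by
    an adaptive weighted elastic net solved by cyclical coordinate descent.
    Includes ten-fold cross-validation tuning, sure independence screening,
    missingness filtering and standardization, a replicated simulation study
    with AR(1)-correlated block-sparse designs, repeated-cross-validation
    stability analysis with signature extraction, and a boxplot-comparison
    inference metric (distance between medians as a fraction of overall
    visible spread) for comparing test-error distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    pheatmap,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
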