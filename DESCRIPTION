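Package: isoqsar
Title: QSAR Modelling of Hsp90 Inhibitors with Combined Data-Splitting
    Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and validating quantitative
    structure-activity relationship (QSAR) models of the Hsp90
    inhibitory activity (pIC50) of 3,4-isoxazolediamides from large
    molecular-descriptor matrices. Implements descriptor preprocessing
    (constant/near-constant removal and greedy collinearity pruning),
    combined data-splitting feature selection (CDFS) with partial-F
    stepwise multiple linear regression, genetic-algorithm descriptor
    selection with cross-validated NIPALS partial least squares fitness
    (GA-PLS), leave-one-out and leave-n-out Q2 statistics,
    Y-randomization, and a leverage-based applicability domain with
    Williams plots. Ships published six-descriptor MLR and GA-PLS
    prediction equations and activity tables as fixtures, plus a seeded
    synthetic-data generator emulating the structure of the original
    descriptor matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
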