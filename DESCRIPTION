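Package: cytodose
Title: Radiation Dose Reconstruction from Combined Dicentric and Micronucleus Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cytogenetic radiation biodosimetry that combine the
    dicentric chromosome assay (DCA) and the cytokinesis-block micronucleus
    (CBMN) assay for machine-learning dose reconstruction. Provides a
    synthetic cohort generator for irradiated-blood aliquot records, low-count
    filtering and assay index computation including a linearized micronucleus
    index, median linear-quadratic quantile regression with bootstrap
    inference and iterative calibration of the linearization constant, a
    quantile regression forest with pluggable baseline learners under repeated
    cross-validation, shadow-feature (Boruta-style) selection, exact Shapley
    attribution, partial dependence profiles, and assay-ablation significance
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    quantreg,
    ranger,
    glmnet,
    e1071,
    xgboost,
    rpart
Config/testthat/edition: 3
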