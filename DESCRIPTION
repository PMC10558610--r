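Package: diabscreen
Title: Diabetes Screening Indices and Penalized Selection for LMIC Survey Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Derives the standard catalogue of anthropometric and biomarker
    screening indices (BMI family, body shape and roundness indices, visceral
    adiposity index, lipid accumulation product, triglyceride-glucose index,
    lipid ratios) from measured survey quantities with explicit unit handling;
    simulates multi-country survey cohorts with realistic marginals,
    correlation structure, per-country predictor availability masks and a
    configurable logistic outcome model; implements a leakage-free
    preprocessing protocol (eligibility exclusions, covariate imputation,
    min-max rescaling fitted on training data, stratified splitting, minority
    oversampling); fits lasso-penalized logistic regression by iteratively
    reweighted least squares with cyclic coordinate descent, cross-validated
    penalty selection and unpenalized demographic controls; and reports
    confusion-matrix screening diagnostics per country.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite
Config/testthat/edition: 3
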