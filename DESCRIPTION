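Package: promval
Title: External Validation of Prediction Models for Bounded Patient-Reported Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Externally validates linear prediction models of bounded (0-100)
    patient-reported outcome scores such as the EPIC-26 prostate cancer
    instrument. Provides registry-style synthetic cohort simulation with
    ceiling-heavy score distributions and missing-at-random covariates,
    EPIC-26 domain scoring, study-style cohort assembly (inclusion criteria
    and visit-window selection), chained-equation multiple imputation with
    predictive mean matching, a battery of validation statistics
    (calibration-in-the-large and calibration slope by median or mean
    regression, R-squared, MAE, RMSE and a continuous concordance index),
    and pooling of the statistics across imputed datasets with
    calibration-plot reporting.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    nnet,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
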