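Package: predvalid
Title: Semi-Automated External Validation of Clinical Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A validation engine for externally validating clinical
    prediction models on new cohorts. Declarative JSON model
    specifications cover four model families (logistic regression,
    conditional annual-risk logistic, Cox proportional hazards with a
    baseline survival table, and empirical profile lookup). Cohort CSV
    files are mapped onto model covariates through a mapping
    configuration with explicit missing-data policies, and the
    validation core quantifies calibration (intercept, slope, grouped
    calibration table with 95% confidence intervals) and discrimination
    (ROC curve, AUC). A seedable synthetic-cohort generator with known
    miscalibration supports testing without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    pROC
Config/testthat/edition: 3
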