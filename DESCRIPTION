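Package: drindex
Title: Derivation of a Points-Based Risk Index for Early Detection of
    Diabetic Retinopathy from Longitudinal EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, seeded pipeline for deriving an early-warning
    risk index for diabetic retinopathy (DR) from longitudinal electronic
    health record (EHR) tables. Implements window-based feature
    aggregation around a per-patient event of interest (a six-month
    prediction window preceded by a two-year observation window),
    interquartile-range outlier removal, mean aggregation of laboratory
    results, complete-case filtering, bivariate screening (chi-squared,
    Welch t, per-level odds ratios with Woolf confidence intervals),
    ensemble predictor selection (AUC-weighted bootstrap importance from
    gradient-boosted trees followed by a golden-section search for the
    minimal predictor count), and a five-step points scoring method that
    maps logistic regression coefficients onto an integer risk index.
    Ships a seeded synthetic-EHR generator emulating a derivation-like
    diabetic cohort, plus the published 10-predictor scoring table
    (0-160 points) ready for scoring new patients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
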