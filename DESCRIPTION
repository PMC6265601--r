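Package: painvol
Title: Pain Volatility Measurement and Prediction from Pain-App Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying volatility in longitudinal self-reported
    pain severity and predicting future volatility levels from early app-usage
    data. Pain volatility is measured as the mean absolute change between
    consecutive severity ratings in an observation window. A one-dimensional
    k-means clustering step derives a data-driven threshold separating low
    from high volatility users, a feature-extraction step builds a canonical
    130-feature predictor vector per user from first-month records, and an
    experiment layer trains penalized logistic regression, random forest and
    RBF-kernel support vector machine classifiers under stratified k-fold
    cross-validation with optional majority-class subsampling to counter
    class imbalance. A synthetic cohort generator with a known latent
    volatility structure supports end-to-end validation without access to
    proprietary app data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    glmnet,
    randomForest,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
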