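Package: mcnet
Title: Monte Carlo Stabilized Penalty Selection for Regularized Logistic
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stabilizes the cross-validated choice of the lasso/elastic-net
    penalty parameter in penalized logistic regression by repeating K-fold
    cross-validation with fresh random splits and taking the median of the
    per-run optima (the MCglmnet procedure), yielding reproducible biomarker
    signatures. Includes a repeated outer cross-validation wrapper for
    near-unbiased AUC estimation, a synthetic-data generator with calibrated
    signal strength, correlated surrogate predictors and high-dimensional
    noise, stability metrics (signature-size inter-percentile range,
    selection frequency), and a driver for the full 27-scenario simulation
    study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
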