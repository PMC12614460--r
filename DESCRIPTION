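Package: salpclinrisk
Title: Salp Swarm-Optimized Machine Learning for Preoperative Aortic Rupture Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An imbalance-aware clinical risk-prediction pipeline for
    preoperative aortic rupture in acute type A aortic dissection. Provides a
    synthetic cohort generator calibrated to published group-wise summary
    statistics (median and interquartile range for continuous variables, exact
    per-group counts for binary variables), leakage-guarded preprocessing
    (stratified train/validation/test splitting, chained-equation imputation,
    univariate feature screening, SMOTE oversampling, train-fitted
    standardization), a from-scratch Salp Swarm Algorithm hyperparameter
    optimizer with a cross-validated error-rate fitness, an eight-family model
    zoo, a full evaluation surface (confusion matrices, ROC/PR/calibration
    curves, decision-curve net benefit, threshold sweeps) and additive Shapley
    feature attributions, plus an end-to-end reproducible run orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
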