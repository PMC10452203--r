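Package: vocaltab
Title: Transformer-Based Classification of Parkinson's Disease from Vocal Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classifies Parkinson's disease from tabular dysphonia (voice)
    measurements with a tabular transformer: gradient-boosted-tree feature
    selection, per-feature continuous embedding networks, a self-attention
    encoder stack, and an MLP classification head, trained with Adam on
    binary cross-entropy. Includes subject-grouped stratified k-fold
    evaluation with ADASYN oversampling of the minority class on training
    folds, a suite of classical baselines, hyperparameter sweeps, and a
    synthetic-cohort generator that emulates repeated recordings per
    subject, class imbalance, and correlated feature blocks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    jsonlite,
    xgboost,
    e1071,
    randomForest,
    rpart,
    class
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
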