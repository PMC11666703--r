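Package: ppgbp
Title: Blood Pressure Estimation and Hypertension Screening from
    Photoplethysmogram Pulse Wave Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A cuffless blood-pressure toolkit built around single-cycle
    pulse wave analysis of the photoplethysmogram (PPG). Provides a seeded
    synthetic PPG generator with blood-pressure-linked pulse morphology,
    zero-phase Butterworth band-pass preprocessing with skewness-based
    signal quality gating, fiducial-point detection and a 46-feature
    morphological extractor (pulse widths, large artery stiffness index,
    augmentation, inflection-point areas, discrete wavelet coefficient
    statistics), decision-tree Gini-importance feature ranking with
    correlation screening, an AdaBoost.R2 boosting regressor with
    weighted-median combination over pluggable base learners, SMOTE and
    random undersampling for imbalanced hypertension classification, and
    an evaluation suite covering MAE/STD, British Hypertension Society
    grading, confusion-matrix metrics and ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
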