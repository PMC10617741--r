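Package: fallscreen
Title: Multi-Domain Variable Importance and Classification for Falls-Risk Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating older adult fallers from non-fallers
    across balance, gait, clinical, strength and body-composition assessment
    domains. Implements domain-partitioned feature tables, the derived
    biomechanical measures used in falls screening (symmetry angle, Romberg
    and somatosensory ratios, gait-variability MAD percentages, rate of
    torque development, muscle-quality indices), univariate screening
    statistics, dual variable-importance ranking by random-forest Gini
    decrease and leave-one-variable-out partial least squares correlation
    (PLSCA) inertia, Fisher-Jenks natural-breaks selection, probabilistic-PCA
    imputation of missing cells, classification with ROC/Youden and
    leave-one-out cross-validation, between-domain shared-information
    (inertia) analysis with permutation inference, and a correlated
    two-group synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    randomForest,
    Matrix,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
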