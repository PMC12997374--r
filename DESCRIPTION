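Package: spiralselect
Title: Spiral-Search Gravitational Feature Selection and Deep Belief
    Networks for Clinical Tabular Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building early-screening classifiers on small,
    imbalanced clinical tabular datasets such as the chronic kidney
    disease (CKD) laboratory panel.  Implements leakage-safe
    preprocessing (mode/median imputation, high-missingness row
    filtering, category validation, Z-score outlier removal, SMOTE
    inside training folds, standardisation), wrapper feature selection
    by a binary gravitational search algorithm with a logarithmic
    spiral local-search operator, a deep belief network classifier
    pretrained by stacked restricted Boltzmann machines with CD-1 and
    fine-tuned by momentum backpropagation, elephant herding
    optimisation of the network hyperparameters, nested stratified
    cross-validated evaluation with discrimination and calibration
    metrics (Brier score, expected calibration error, calibration
    slope), and exact Shapley-value attribution of the selected
    biomarkers.  A synthetic-data generator emulating the UCI CKD
    schema makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    caret
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
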