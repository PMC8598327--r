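Package: dsnrisk
Title: Deep-Stacking Network for Supply-Chain Risk-Level Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-class risk-level classification of heterogeneous supply-chain
    monitoring records with a deep-stacking network: dictionary/one-hot encoding
    and standardization of mixed tabular data, multigranularity padded sliding-window
    scanning into class-probability features, a K-fold out-of-fold stacked cascade of
    diverse base learners, and a Gaussian-mixture fusion head fitted by
    expectation-maximization. Ships a synthetic generator for grain supply-chain
    monitoring records with a recoverable rule-based ground truth, an evaluation
    suite (accuracy, precision, recall, F1, confusion matrices), a hyperparameter
    sweep harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    xgboost,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
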