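Package: nlrtrack
Title: Recurrence Detection from Longitudinal NLR and PLR Trajectories
    after Chemoradiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting head-and-neck cancer recurrence from
    irregularly sampled post-treatment blood counts.  Computes windowed
    meta-features of the neutrophil-to-lymphocyte ratio (NLR) and the
    platelet-to-lymphocyte ratio (PLR) from longitudinal laboratory
    records, augments training data by temporal splitting of recurrent
    trajectories, trains a suite of classifiers (logistic regression,
    random forest, gradient boosting, and a feed-forward neural network)
    under stratified group-aware cross-validation, and performs
    sensitivity-based recursive feature elimination driven by the dynamic
    range of the model response.  Includes a synthetic cohort generator
    that emulates post-chemoradiotherapy surveillance data for method
    development and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    ranger,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
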