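Package: rsfas
Title: Rough Set on Fuzzy Approximation Space Pipeline for Stage-Based
    Cancer Survival Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an uncertainty-aware pipeline for predicting the
    stage of colorectal cancer from clinical covariates and gene-expression
    profiles.  Variance-inflation-factor screening removes multicollinear
    attributes; a censoring-aware Weibull survival model imputes missing
    event indicators and yields stage-stratified survival estimates with
    bootstrap confidence intervals, concordance and likelihood-ratio
    statistics; rough sets on a fuzzy approximation space discretize the
    numeric attributes into alpha-equivalence classes; and hand-implemented
    unidirectional and bidirectional LSTM classifiers predict the stage from
    the resulting ordinal profiles.  Evaluation utilities cover one-vs-rest
    confusion metrics, Cohen's kappa, Kullback-Leibler divergence, ROC-AUC
    and stratified k-fold cross-validation, and a synthetic-data generator
    emulates the attribute structure the pipeline assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
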