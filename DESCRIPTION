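Package: somnomark
Title: Polysomnography Feature Pipelines for Non-Invasive Prediction of CSF
    Alzheimer Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Signal processing and machine-learning tools to estimate the
    cerebrospinal-fluid Alzheimer core biomarkers (amyloid-beta 1-42,
    phosphorylated tau, total tau; pg/ml) from overnight polysomnography:
    EDF input/output, AASM-style preprocessing (resampling, zero-phase
    Butterworth filtering, stage decomposition, artifact exclusion),
    time-domain, non-linear (sample entropy, Lempel-Ziv, Higuchi fractal
    dimension, Shannon entropy) and Welch spectral feature extraction,
    conventional sleep-parameter derivation (TST, sleep efficiency, AHI, ODI,
    CT90), correlation- and PCA-based feature selection with leak-free
    train/test handling, a fifteen-model classical regression zoo benchmarked
    by mean absolute error, and a synthetic PSG cohort generator for fully
    reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    glmnet,
    xgboost,
    randomForest,
    ranger,
    e1071,
    caret,
    ggplot2,
    tools,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
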