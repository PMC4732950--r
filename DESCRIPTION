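Package: respvar
Title: Nonlinear Complexity Analysis of Breathing Pattern Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the complexity of breath-by-breath
    respiratory dynamics. Extracts inter-breath interval (IBI) and lung
    volume (LV) series from respiratory inductive plethysmography
    waveforms, and computes four nonlinear indices per subject: the
    detrended fluctuation analysis scaling exponent, sample entropy,
    cross-sample entropy between IBI and LV, and the largest Lyapunov
    exponent estimated by the Rosenstein algorithm with embedding
    parameters selected by average mutual information and false nearest
    neighbors. Includes a weighted sparse representation classifier
    evaluated under leave-one-out cross-validation, sequential forward
    feature selection, ROC analysis with exact binomial confidence
    intervals, and a synthetic-cohort simulator with controllable
    long-range correlation, regularity, chaoticity and IBI-LV coupling
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pROC,
    pracma,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
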