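Package: vagdx
Title: Vibroarthrographic Signal Simulation, Preprocessing and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for knee-joint vibroarthrography (VAG): simulation of
    two-channel (acoustic + knee-angle encoder) recordings with
    severity-dependent transient bursts, movement-cycle segmentation by
    encoder slope detection, signal cleaning by ensemble empirical mode
    decomposition (EEMD) with residual-trend removal, twelve time-domain
    signal measures (mean, rectified mean, RMS, peak, peak-to-peak, crest,
    impact and shape factors, variance, kurtosis, M6A, M8A), neighborhood
    component analysis (NCA) feature selection with cross-validated
    regularization, multilayer perceptron and radial-basis-function network
    classifiers, and confusion/ROC evaluation for healthy-versus-osteoarthritis
    discrimination in open and closed kinetic chains.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
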