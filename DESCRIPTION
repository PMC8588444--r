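Package: phasesom
Title: Phase-Synchrony EEG Connectivity and SOM-Based Anomaly Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-group EEG functional-connectivity studies based on
    phase synchronization. Recordings are band-decomposed with zero-phase
    least-squares FIR filters, instantaneous phases are extracted with the
    Hilbert transform, and channel-pair synchrony is measured with the phase
    locking value or the circular correlation coefficient. Group differences
    are detected two ways: per-connection Mann-Whitney tests with
    Benjamini-Hochberg false-discovery-rate control, and a one-class anomaly
    detector that trains a self-organizing map on control connectivity
    vectors, scores subjects by quantization error, and separates groups with
    a Bayesian threshold on that error. Includes a synthetic coupled-source
    EEG cohort generator with planted per-band coupling for end-to-end
    validation, subject-stratified cross-validation, ROC/AUC metrics and
    label-permutation significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
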