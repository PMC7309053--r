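Package: ecgid
Title: ECG Biometric Identification with Bidirectional LSTM Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for person identification from single-channel
    electrocardiogram (ECG) recordings. Implements derivative/moving-average
    preprocessing with median-range amplitude normalization, heartbeat
    segmentation by fixed time windows or R-peak detection with beat grouping,
    a long short-term memory (LSTM) classifier built from the gate equations
    up (stackable unidirectionally or bidirectionally, with sum-rule late
    fusion of per-timestep class scores), an Adam/cross-entropy training
    harness with stratified splits, a multi-class precision/recall/accuracy/F1
    evaluation suite, a seeded multi-subject synthetic ECG generator with
    exact ground truth, and readers/writers for WFDB-format records.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
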