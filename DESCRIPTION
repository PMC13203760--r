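Package: tinybeat
Title: Heartbeat Classification with a Compact Quantized 1D
    Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for single-lead ECG arrhythmia
    screening on microcontroller-class hardware: Butterworth zero-phase
    band-pass filtering, Pan-Tompkins QRS detection, 250-sample beat
    segmentation with per-beat min-max normalization, a compact 1D
    convolutional network for three AAMI-style beat classes (normal,
    ventricular, supraventricular), post-training full-integer INT8
    quantization with calibration, an integer-only inference engine that
    emulates execution without a floating-point unit, memory-footprint
    accounting, and AAMI-style evaluation (confusion matrices, weighted
    precision/recall/F1, one-vs-rest AUC, stratified splits and five-fold
    cross-validation). Includes a seeded synthetic ECG generator with
    ground-truth R-peak positions and labels, plus a minimal WFDB
    reader/writer, so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
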