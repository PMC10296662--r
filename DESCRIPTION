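Package: emgrip
Title: Surface-EMG Gesture Classification and Myoelectric Gripper Control
Version: 0.1.0
Authors@R:
    person("emgrip", "developers", email = "emgrip@example.org", role = c("aut", "cre"))
Description: A tested pipeline for myoelectric prosthesis control from
    three-channel surface electromyography (sEMG): a protocol-driven synthetic
    session generator with known ground truth, CSV recording input/output and
    window segmentation, RMS-envelope smoothing with peak-dynamic
    normalization, time-domain feature extraction (RMS subwindows and the
    MAV-family statistics), a small five-layer multilayer perceptron trained
    with Adam (multiclass softmax and binary sigmoid variants), stratified
    k-fold cross-validated evaluation with confusion analysis and a
    window-duration sweep, and a confidence-gated streaming classifier that
    maps predictions to virtual gripper and turn-base motor commands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
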