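Package: mhdnet
Title: R-Peak Detection in MHD-Corrupted ECG with Self-Organizing
    Operational Segmentation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects R-peaks in electrocardiograms recorded inside MRI
    scanners, where the magnetohydrodynamic (MHD) effect inflates the
    T-wave until it can eclipse the QRS complex. Frames detection as 1D
    semantic segmentation with a self-organizing operational neural
    network (generative neurons with Taylor-style polynomial kernels),
    attention-gated skip connections and a feature-pyramid output head.
    Includes a WFDB-compatible reader/writer, zero-phase bandpass and
    powerline-notch preprocessing, pulse-train labelling, subject-wise
    cross-validation, tolerance-window detection scoring, and a synthetic
    3-lead ECG generator with a controllable MHD-like artifact.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    signal,
    withr
Config/testthat/edition: 3
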