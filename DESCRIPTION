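Package: cyclebeat
Title: Cyclic Latent-Trajectory Autoencoding of Single-Lead ECG for Atrial Fibrillation Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A three-stage pipeline for detecting atrial fibrillation from
    single-lead electrocardiograms. Records are segmented into heartbeats or
    slices anchored on Pan-Tompkins R-peak detection, each segment is encoded
    as the parameters of a cyclic latent trajectory (frequency, phase shift
    and time-constant shape coefficients) by a small autoencoder, and the
    per-beat embeddings are aggregated (mean or bidirectional LSTM) into a
    record-level representation for rhythm classification with cross-validated
    metric reporting. Includes a synthetic single-lead ECG generator with
    known beat times and rhythm classes, readers and writers for WFDB records
    and annotations, and a plain-text interchange format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
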