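Package: bisre
Title: Data-Driven Reconstruction of the Bispectral Index Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how the Bispectral Index (BIS), a proprietary
    0-98 electroencephalography-derived measure of anaesthetic depth, can be
    reconstructed from its published subparameters. Implements extraction of
    the five EEG subparameters (burst suppression ratio, 95% spectral edge
    frequency, electromyographic power, relative beta ratio and SyncFastSlow)
    from raw waveforms; a deterministic BIS estimator built from a published
    four-node decision tree and five per-range linear regressions; and the
    full discovery pipeline that recovers that estimator from per-second
    monitor data: histogram boundary detection, class-balanced sampling, a
    bagged ensemble of classification trees, and RANSAC robust regression,
    together with the associated validation metrics. A synthetic-data
    generator emulating per-second anaesthesia cases and raw EEG with
    prescribed spectral content makes every stage testable without access to
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rpart,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
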