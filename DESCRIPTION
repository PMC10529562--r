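Package: ecgfuse
Title: Multi-Database ECG Heartbeat Integration and Arrhythmia Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for merging heterogeneous annotated electrocardiogram
    databases into a single heartbeat classification dataset. Reads WFDB-style
    records (format 212 signal files and MIT annotation files, with a
    plain-text fallback), extracts fixed-length heartbeats around annotated R
    peaks using a heart-rate-derived sampling window, unifies sampling
    frequencies by band-limited resampling, harmonizes beat codes onto a
    16-class labelling scheme, and applies per-beat self-normalization so that
    amplitude scale and offset differences between source databases cancel.
    Includes a seeded synthetic multi-database ECG generator, stratified
    train/test splitting, reference classifiers (a 5-layer fully connected
    network and a 12-layer 1-D residual network trained with Adam), and an
    evaluation harness producing per-class precision/recall/F1 tables,
    confusion matrices and preprocessing-method comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
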