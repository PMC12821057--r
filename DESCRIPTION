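Package: ecglvm
Title: Left Ventricular Mass Estimation from 12-Lead ECG with Temporal
    Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates left ventricular mass (LVM, grams) from 12-lead
    electrocardiograms using lead-group-specific temporal convolutional
    encoders fused with demographic and automatic ECG-parameter branches.
    Provides a seeded synthetic ECG-cohort simulator whose waveform
    morphology encodes a known LVM, signal preprocessing (zero-phase
    band-pass filtering, R-peak detection, synchronized single-heartbeat
    extraction, lead grouping by electrical plane or coronary territory),
    LVM-sorted systematic cross-validation folds, sex-specific model
    fitting, LVM/LVH evaluation metrics, and gradient-saliency analysis of
    ECG-segment importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
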