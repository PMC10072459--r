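Package: cdecg
Title: Compressed-Domain Classification of ECG Heartbeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying electrocardiogram (ECG) heartbeats directly
    in the compressed domain. Beats are cut from annotated ambulatory
    recordings (WFDB format) as fixed-length R-peak-centered windows, mapped
    to AAMI arrhythmia super-classes, compressed by a small learned
    one-dimensional convolutional network to a chosen compression ratio, and
    classified by a lightweight parallel-branch convolutional network without
    ever reconstructing the signal. Includes SVD and PCA baseline
    compressors, a synthetic beat generator for desk-scale experiments,
    joint end-to-end training with an adaptive learning rate, multi-class
    evaluation metrics (confusion matrices, macro precision/sensitivity/F1,
    ROC and PR curves), and a benchmark harness over compression ratios,
    compression methods and classifier variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
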