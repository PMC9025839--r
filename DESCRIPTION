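Package: fwrfe
Title: Weight-Norm Recursive Feature Elimination for CNN-Based ECG Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for binary normal/abnormal classification of
    12-lead electrocardiograms. Three one-dimensional convolutional networks of
    different depth are trained independently as feature extractors; each
    extractor's flattened final-pooling activations are pruned by recursive
    feature elimination driven by the sum of squared first-hidden-layer weights
    (FW-RFE); the retained features are concatenated and classified by a single
    sigmoid unit. Includes a controllable synthetic 12-lead ECG generator,
    cohort construction with patient-disjoint splits, zero-phase band-pass
    preprocessing, a minimal WFDB reader/writer, and confusion-matrix based
    evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
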