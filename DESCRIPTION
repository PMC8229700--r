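Package: heartprint
Title: Single-Heartbeat ECG Biometric Recognition with Scalogram Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for electrocardiogram (ECG) based biometric identification and
    verification from a single heartbeat. Provides a synthetic multi-subject,
    multi-session ECG generator with ground-truth fiducials, R- and P-peak
    detection (curvature candidates with adaptive thresholding and search-back;
    Hilbert-envelope P search), four heartbeat segmentation schemes (blind,
    R-centered, R-R, P-P) with averaging-based augmentation, continuous wavelet
    transform scalogram imaging, Kullback-Leibler biometric system entropy of
    genuine versus imposter score distributions, a small residual convolutional
    network classifier trained with stochastic gradient descent, and the full
    identification/verification evaluation protocol (stratified and session-wise
    cross-validation, FAR/FRR/HTER, McNemar test with continuity correction,
    Fisher-Z population summaries, cumulative accuracy distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    EBImage,
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
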