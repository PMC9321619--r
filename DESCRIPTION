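Package: siamvitals
Title: Contactless Heart and Respiration Rate Estimation with a Multitask Siamese Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for camera-based vital-sign estimation. Two
    facial regions of interest (forehead and cheek) are cropped from a video
    stream and fed to a two-branch convolutional network with shared weights
    and convolutional block attention, which predicts per-frame
    photoplethysmography (PPG) and respiration traces simultaneously. Heart
    and respiration rates are then derived by Butterworth bandpass filtering
    and mean inter-peak-interval analysis, and compared against reference
    traces with correlation and error metrics. A synthetic region-of-interest
    video generator with embedded cardiac colour modulation and respiratory
    modulation makes the whole pipeline runnable and testable without any
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    png
LinkingTo:
    Rcpp
Config/testthat/edition: 3
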