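Package: ecgfusion
Title: Two-Stage ECG Anomaly Detection with Spectrograms and Handcrafted Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects structural anomalies in two-lead ambulatory ECG in two
    stages: abnormal 3-second rhythm windows first, then abnormal heartbeats
    inside the remaining normal rhythm. Each stage classifies a short-time
    Fourier transform spectrogram merged with a fixed-schema handcrafted
    feature vector (R-peak counts from two independent detectors, statistical
    moments, and P-QRS-T interval measurements) inside a convolutional network
    with a feature-merging head, followed by two-lead score fusion. Includes a
    seedable synthetic two-lead ECG generator with beat and rhythm
    annotations, a minimal WFDB reader/writer, Pan-Tompkins and Shannon
    energy envelope Hilbert-transform R-peak detectors, an ecgpuwave-style
    delineator, and confusion-matrix evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
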