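Package: snorescreen
Title: Snore Event Detection and Classification from Nocturnal Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A two-stage pipeline for acoustic screening of obstructive sleep
    apnea-hypopnea syndrome (OSAHS) from overnight ambient-microphone
    recordings. Stage one segments snore events with an adaptive multi-feature
    endpoint detector: spectral-subtraction denoising, 25 ms/10 ms Hamming
    framing, four frame-level features (short-time energy, spectral entropy,
    zero-crossing rate, spectral centroid), per-window statistical thresholds,
    majority voting, gap merging and minimum-duration filtering. Stage two
    classifies each segment from its 128x128 log-Mel spectrogram with a hybrid
    network: an ECA-augmented ResNet18 backbone feeding a bidirectional GRU.
    The neural-network layers (convolution, batch normalisation, efficient
    channel attention, GRU, Adam) are implemented in the package with Rcpp
    kernels for the convolutions. A seeded synthetic-audio module generates
    nocturnal recordings with known snore ground truth and a two-class
    spectrogram dataset so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
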