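Package: tfsldecode
Title: Time-Frequency Synchronization Likelihood Features for Single-Trial EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Extraction of time-frequency resolved synchronization likelihood
    (TFSL) features from epoched multichannel EEG and single-trial decoding of
    binary preference decisions. Provides a synthetic multichannel generator
    with known class-dependent inter-channel coupling, preprocessing
    (mastoid re-referencing, zero-phase Butterworth band-pass filtering,
    epoching), the synchronization likelihood estimator with per-band
    time-delay embedding, F-ratio feature ranking with temporal and spatial
    discriminability profiles, a small Levenberg-Marquardt-trained
    feedforward network classifier, sequential forward feature selection,
    pooled (CGM) and per-participant (PAM) evaluation protocols, and
    quasi-randomization chance estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
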