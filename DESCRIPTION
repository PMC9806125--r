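Package: pgesdetect
Title: Hybrid Unsupervised and Supervised Detection of Postictal
    Generalized EEG Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the end of postictal generalized EEG suppression
    (PGES) in multi-channel scalp EEG. Signals are decomposed by
    empirical mode decomposition and Hilbert spectral analysis; a
    low-frequency Hilbert amplitude map summarizes each recording's
    artifact burden; K-means groups recordings with similar artifact
    patterns; cluster-oriented sample-weighted random forests classify
    1-second epochs as suppressed or not; and the first intermittent
    slow wave is reported as the PGES end. Includes a synthetic
    postictal EEG generator with known ground truth, recording-based
    time-distance metrics (TD_avg, Acc_5s, Acc_10s), a leave-one-out
    evaluation driver, minimal EDF input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ranger,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
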