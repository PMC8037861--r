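Package: eegalert
Title: EEG-Based Inattention Detection and Alerting for UAV Operators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A brain-computer-interface pipeline that detects lapses of operator
    attention from multichannel EEG and raises recovery alerts. Raw EEG is
    band-pass filtered and decomposed into delta/theta/alpha/beta amplitudes by
    sliding-window FFT, summarized by adaptive autoregressive (AAR) coefficients
    tracked with recursive least squares, and reduced by PCA. Windows are labeled
    attention or inattention from the variance of flight telemetry (altitude and
    velocity), and a pair of Gaussian hidden Markov models classifies feature
    sequences by forward log-likelihood. The package includes a synthetic
    session simulator with known ground truth, an alerting monitor with a
    closed-loop responsive simulant, an SVM baseline, and evaluation tools
    (confusion metrics, label-ratio and band diagnostics, attention-recovery
    comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
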