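Package: eegsample
Title: Sampling-Based Feature Extraction and Detection of Multicategory EEG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects multicategory EEG signals (e.g. the five-class
    healthy/interictal/seizure problem) by segmenting each per-class
    recording into non-overlapping time windows, selecting representative
    time points by random sampling or optimum-allocation sampling with
    Cochran's sample-size formula and finite-population correction,
    extracting eleven statistical features per channel, and classifying
    with k-nearest neighbours, ridge-penalized multinomial logistic
    regression, or one-vs-one RBF support vector machines under a
    repeated, stratified cross-validated protocol.  Includes a synthetic
    corpus generator emulating the per-channel ASCII layout of the public
    Bonn EEG corpus so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
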