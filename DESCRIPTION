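Package: dmelm
Title: Moth-Flame Optimized Extreme Learning Machines for EEG Seizure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classification of single-channel EEG segments for epileptic
    seizure detection. Segments are decomposed with a level-4 Daubechies-2
    discrete wavelet transform, summarized by six per-sub-band statistics,
    and classified by an extreme learning machine (ELM) whose output weights
    are solved in closed form. A moth-flame optimizer (MFO) tunes the
    classifier's parameters against a cross-validated objective (DM-ELM).
    Includes a synthetic EEG generator with normal, interictal and ictal
    classes, readers for Bonn-style ASCII segment trees, and evaluation
    utilities (stratified cross-validation, activation sweeps, validation
    curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
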