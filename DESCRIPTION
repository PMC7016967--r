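Package: driversense
Title: Multimodal Bio-Sensing Features and Classification for Driver Awareness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Feature extraction, fusion and classification for driver-awareness
    studies that combine EEG, photoplethysmography (PPG), galvanic skin response
    (GSR) and facial-landmark video. Implements conditional-entropy channel-pair
    features and band-power topographic RGB images for EEG, heart-rate/pNN50 and
    statistical descriptors plus spectrogram images for PPG and GSR, geometric
    landmark features with per-trial aggregation for faces, a pluggable
    4096-dimensional image-embedding contract with a deterministic stub backbone,
    extreme learning machine (ELM) and LSTM classifiers, leave-one-subject-out
    cross-validation with accuracy/AUC and test statistics, and a synthetic
    multimodal recording generator so the whole pipeline runs end-to-end without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    MASS,
    png,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
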