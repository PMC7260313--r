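Package: eegmicronet
Title: Microstate and Visibility-Graph Network Features for Interictal EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discriminating patient groups from short interictal
    multichannel EEG. Implements per-channel signal descriptors (energy,
    Shannon/spectral/Renyi entropies, box-counting, Higuchi and Katz fractal
    dimensions), functional connectivity networks built from horizontal
    visibility graph degree-sequence synchronization with weighted graph
    measures, and EEG microstate segmentation via polarity-invariant modified
    K-means with occurrence, duration and coverage statistics. A synthetic
    multichannel EEG generator with planted microstate structure supports
    calibration and power analysis, and a patient-wise paired
    cross-validation harness evaluates classifier batteries with
    leave-one-band-out and leave-one-feature-out importance protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    igraph,
    jsonlite,
    e1071,
    randomForest,
    rpart,
    class,
    xgboost,
    pROC,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
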