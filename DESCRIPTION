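Package: eegselect
Title: EEG Channel Selection for Biometric Identification via a Hybrid
    Flower Pollination / Beta-Hill Climbing Wrapper
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper-based selection of electroencephalogram (EEG) channels
    for biometric user identification. Per-channel autoregressive
    (Yule-Walker) or discrete-wavelet features feed a classifier-wrapped
    fitness (validation accuracy of an RBF support vector machine by
    default), and a binary Flower Pollination Algorithm hybridized with
    beta-hill climbing local search explores channel subsets through a
    sigmoid transfer function. Includes a synthetic multi-subject EEG
    cohort generator with planted discriminative channels, notch/band-pass
    preprocessing, standalone FPA and beta-hill climbing baselines, and an
    experiment driver with paired significance tests and
    channel-selection-frequency reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    MASS,
    class,
    nnet,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
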