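Package: etholarva
Title: Behavioral Phenotyping of Drosophila Larva Mechanosensory Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for quantifying Drosophila larva responses
    to air-puff stimulation from multi-worm-tracker style contour and spine
    time series. Provides tracker-output ingestion and cleaning, geometric
    and kinematic feature extraction, hidden-Markov-model head-tail
    disambiguation by Viterbi decoding, a multilayer discrete-action
    classifier with rule-based regularization, ethogram and behavioral
    transition statistics, and a generalized likelihood-ratio framework for
    hit detection in large genetic screens. A synthetic larva-kinematics
    generator with ground-truth action labels makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    randomForest,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
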