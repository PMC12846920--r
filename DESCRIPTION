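Package: extinctRSA
Title: Representational Similarity Analysis of Context-Dependent Fear
    Extinction in Intracranial EEG
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for three-phase (ABC)
    fear-conditioning and extinction experiments recorded with stereotactic
    intracranial EEG. Generates pseudo-randomized trial schedules under
    run-length and context-balance constraints, synthesizes multichannel
    recordings with 1/f background, plantable theta-band safety effects and
    item-/context-specific spectral-spatial signatures, and implements the
    full analysis chain: zero-phase filtering, bipolar referencing,
    epileptiform artifact detection, epoching, variable-cycle Morlet
    time-frequency decomposition, sliding-window Spearman representational
    similarity metrics (item stability, context specificity), cross-region
    trial-level coordination maps, cross-phase reinstatement metrics, and
    cluster-based permutation inference with trial-label shuffling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
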