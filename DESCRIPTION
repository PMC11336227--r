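Package: prestim
Title: Pre-Stimulus Oscillatory EEG Analysis with Cluster Permutation
    Statistics and Cross-Experiment Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how ongoing (pre-stimulus) neural
    oscillations relate to the perceived valence of subsequently presented
    ambiguous emotional faces.  Provides a synthetic-EEG cohort generator
    (1/f background, oscillatory bursts, valence-dependent pre-stimulus
    band-power effects, negativity-biased ratings), epoch-level containers
    with BrainVision/EDF import, common-average referencing and trial
    equalization, sliding Hanning-taper time-frequency decomposition with
    decibel baseline correction, nonparametric cluster-based permutation
    statistics over channel x frequency x time (paired and covariate
    designs), within-subject and leave-one-participant-out cross-experiment
    support-vector-machine decoding with binomial accuracy statistics, and
    behavioral negativity-bias analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
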