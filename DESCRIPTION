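Package: tntphysio
Title: Cardiac and EEG Correlates of Memory Suppression in Think/No-Think Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for stimulus-evoked cardiac deceleration and its
    EEG oscillatory correlates in Think/No-Think (TNT) memory-suppression
    experiments. Converts heartbeat (R-peak) series into baseline-referenced
    evoked heart-rate timecourses, runs pointwise paired contrasts with
    Benjamini-Hochberg false discovery rate control, extracts times of
    interest, and computes per-participant cardiac inhibition scores.
    Provides multitaper time-frequency decomposition with percent-change
    baselining, nonparametric cluster-based permutation tests over
    channel x frequency x time arrays, exact Mann-Whitney rank tests with
    common-language effect sizes, and TNT behavioral indices (intrusion
    timecourses, suppression-induced forgetting, group splits). A synthetic
    cohort generator with known ground truth emulates the cardiac, EEG and
    behavioral structure of such studies so that the whole pipeline can be
    validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
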