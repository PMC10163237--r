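Package: socialca1
Title: Reward-Expectation and Social-Identity Coding in Hippocampal CA1
    Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for head-fixed Go/NoGo social discrimination
    sessions imaged with two-photon calcium microscopy. Scores trials and
    detects high-performance periods, converts raw per-ROI fluorescence into
    dF/F0 calcium-event traces (median filter, sliding-percentile drift
    correction, kernel-density baseline, two-pass robust event threshold),
    quantifies per-neuron trial-type and stimulus discriminability with the
    d-prime index and permutation nulls, classifies neurons across
    contingency-reversed session pairs into reward-, no-reward- and
    identity-selective classes with 3x3 contingency inference, and performs
    time-resolved population decoding (leave-one-trial-out linear SVM,
    one-vs-rest multiclass, cross-day transfer) with cluster-based
    permutation significance. A synthetic-session generator plants known
    ground-truth neuron classes so that every stage is validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
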