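Package: cbci
Title: Anytime Collaborative Brain-Computer Interfaces for Group Decision-Making
Version: 0.1.0
Authors@R: person("Open", "Neuro Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to build and evaluate collaborative brain-computer interfaces
    (cBCIs) that support two-alternative perceptual group decisions. The package
    estimates per-trial decision confidence for each group member from
    common-spatial-pattern (CSP) log-variance EEG features, reconstructed
    response times and (optionally) self-reported confidence, using
    cross-validated random forests; aggregates member votes by
    confidence-weighted majority; and provides an "anytime" engine that emits a
    group decision every 100 ms after the first response, morphing each member
    between estimators as their data arrive. Because comparable public
    recordings do not exist, a synthetic-experiment simulator (behaviour,
    response-locked EEG epochs, and video frame streams with hidden stimulus
    onsets) generates statistically realistic datasets, and the evaluation layer
    reproduces the standard analysis machinery (pointwise Wilcoxon ERP masks,
    Holm-adjusted pairwise comparisons, bootstrap standard errors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
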