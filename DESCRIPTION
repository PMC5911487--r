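Package: FollowerScan
Title: Follower-Cell Detection in Two-Photon Calcium Imaging by
    Circular-Shuffle Rank-Sum Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying neurons whose trial-locked calcium
    responses follow single-cell stimulation ("follower" cells) in
    two-photon imaging experiments. Implements per-trial delta-F/F response
    extraction, a circular-shuffle null with Wilcoxon rank-sum z scoring
    and sham-calibrated classification thresholds, a spike-insertion
    simulator for sensitivity calibration, comparator detection criteria,
    and field-of-view level population (z-median) analyses. Includes a
    synthetic OGB-like fluorescence trace generator so the full pipeline
    can be exercised and validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
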