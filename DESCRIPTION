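Package: dcgnet
Title: Multiscale Data Cloud Geometry for Functional Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multiscale clustering of ROI-by-ROI correlation matrices via
    data cloud geometry: a temperature-indexed power transformation turns a
    correlation matrix into a similarity matrix, an ensemble of regulated
    random walks with node removal summarizes it into a cluster-sharing
    probability matrix, and spectral eigengap counting plus hierarchical-tree
    pruning yield one clustering level per temperature.  Tools to sweep
    temperature, detect phase transitions and tune each subject's geometry to
    a common cluster count; coarse-scale intra/inter-regional connectivity
    retention features with two-sample t screening; fine-scale motif
    configurations, group motif domains with prevalence, and jackknifed
    odds / missing-motif features; and a leave-one-out cross-validated
    logistic classifier with a prevalence-threshold sweep.  Includes a
    synthetic cohort generator with planted pair motifs, anatomical region
    blocks and group-differential structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
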