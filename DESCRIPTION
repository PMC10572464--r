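Package: conntfce
Title: Threshold-Free Cluster Enhancement for ROI-to-ROI Functional
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Group comparison of resting-state ROI-to-ROI functional
    connectivity matrices with threshold-free cluster enhancement (TFCE)
    and permutation-based family-wise error control, plus the fixed
    threshold network-based statistic (NBS) as a comparator.  Includes a
    synthetic multi-subject BOLD time-series generator with a planted
    edge-cluster effect and clinical-score coupling, Pearson/Fisher-z
    connectivity estimation with motion/global-signal scrubbing, edgewise
    two-sample t and one-way F maps, hierarchical ROI sorting, cluster-of
    interest ANOVA and clinical-score correlation, and delimited-text
    report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
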