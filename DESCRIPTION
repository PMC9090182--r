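Package: muscnet
Title: Weighted-Voting Fusion of Multi-Metric Brain Functional
    Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs static and sliding-window dynamic brain functional
    connectivity networks (BFCNs) from region-of-interest BOLD time series
    under five pairwise association metrics (Pearson, Spearman, Kendall,
    cosine similarity, and a from-scratch maximal information coefficient),
    selects discriminative edges with filter tests (t-test, Wilcoxon
    rank-sum, Kolmogorov-Smirnov), and classifies subjects by linearly
    fusing decision scores of per-metric linear support vector machines
    (the MuscNet weighted-voting model), evaluated by leave-one-out and
    nested leave-one-out cross-validation.  Includes a synthetic BOLD
    cohort generator with planted differential connectivity for end-to-end
    validation, selection-frequency reporting of edges and ROIs, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    e1071,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
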