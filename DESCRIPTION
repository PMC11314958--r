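Package: connectolesion
Title: Structural Brain Network Topology and Virtual-Lesion Resilience
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Graph-theoretic analysis of streamline-weighted structural
    connectomes in case-control neuropathology cohorts. Provides proportional
    thresholding and binarization of weighted connectivity matrices, binary
    graph measures (global efficiency, clustering coefficient, eigenvector
    centrality), virtual single-node-failure resilience (change in global
    efficiency after regional node removal), covariate-adjusted rank-based
    statistics (Jaeckel dispersion minimization with Wilcoxon scores, partial
    Spearman correlation, exact signed-rank and Mann-Whitney tests,
    Benjamini-Hochberg correction), and a seeded synthetic cohort generator
    emulating a postmortem Parkinson disease study design for end-to-end
    pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
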