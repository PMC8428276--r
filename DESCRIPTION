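Package: trajtree
Title: Rooted Single-Cell Trajectory Trees with Landmark ISOMAP and
    Principal Trend Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds rooted developmental trajectories over single-cell
    clusters from a user-specified root and structured leaf groups. The
    pipeline covers count-matrix preprocessing (filtering, library-size
    normalisation, variable-feature selection, PCA), kNN-graph community
    detection with a neighbourhood-size sweep, 3-D landmark ISOMAP
    embedding seeded by per-cluster graph hubs, a constrained spanning
    tree over clusters, cell-level pseudotime, and sparse-smooth
    principal trend analysis of expression along branches. A
    branching-lineage negative-binomial count simulator with ground-truth
    topology and pseudotime makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    Matrix,
    ape,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    pheatmap,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
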