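Package: paretocell
Title: Pareto Task Inference for Stratified Single-Cell Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects low-dimensional polytopes (simplices) in within-cell-type
    single-cell expression variation, the geometric signature of Pareto
    optimality among competing cellular tasks. Provides quality control and
    normalization for donor-tissue-cell-type strata, linear-scale principal
    component analysis with artifact-component removal, archetypal simplex
    fitting with explained-variance elbow selection, a t-ratio shuffle test of
    polytope significance, per-vertex marker-gene enrichment with
    Benjamini-Hochberg control, aggregation of stratum significance to
    cell-type calls with a Storey pi0-corrected false discovery rate, and
    cross-donor archetype alignment by shared enriched genes. A synthetic
    atlas generator with planted archetypes supports calibration and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    clue,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
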