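Package: spotdecon
Title: Cell-Type Deconvolution of Spatial Transcriptomics Spots by
    Enrichment-Guided Dampened Weighted Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the cell-type composition of spatial transcriptomics
    spots from a single-cell reference. Candidate cell types are first
    selected per spot with a parametric gene-set enrichment (PAGE) score on
    marker-gene fold changes; the composition of the selected types is then
    estimated by constrained weighted least squares with dampened inverse
    fitted-value weights, a cross-validated damping constant, cluster-shared
    weights, and a second round after removal of low-frequency types.
    Includes marker ranking by a Gini specificity score, a coarse-graining
    simulator that bins single-cell-resolution spatial data into pseudo-spots
    with known ground truth, RMSE evaluation split by cell-type presence and
    absence, and a fractional-composition spatial assortativity coefficient.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    MASS,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pracma,
    jsonlite
Config/testthat/edition: 3
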