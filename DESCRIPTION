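Package: scnet
Title: Structural Covariance Network Analysis of ROI Cortical Thickness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares group-level structural covariance networks
    (SCNs) from region-of-interest cortical thickness tables. Provides
    covariate residualization, group Pearson covariance matrices, exact-density
    binarization over a density grid, regional (degree, betweenness, nodal
    efficiency) and global (global/local efficiency, clustering, path length,
    small-worldness) graph metrics against degree-preserving rewired null
    ensembles, and permutation-based inference on area-under-the-curve
    statistics with false discovery rate correction. Includes a synthetic-data
    generator with planted covariance structure so the full pipeline can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
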