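Package: ductnet
Title: Quantitative Analysis of Developing Ductal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying spatially embedded ductal networks of
    branched secretory organs and for modeling their development. Computes
    standard network statistics for digitized duct skeletons (total length,
    cost and performance relative to the Euclidean minimum spanning tree,
    adjacency-trace polygon counts, clustering, distances to the exit node,
    network dimension), simulates plexus formation by stochastic redundant
    linking of new lumens, remodels a plexus into a tree by pruning
    lowest-flux redundant ducts under steady-state diffusion toward the
    exit, and analyzes the adaptation of duct diameter to the flux each
    duct carries. Includes generators for synthetic plexus- and tree-like
    networks so every stage of the pipeline can be exercised without
    microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
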