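Package: allopath
Title: Dynamical Network Analysis of Allosteric Pathways in Protein
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds residue-level dynamical networks from equilibrium
    molecular trajectories and traces allosteric communication pathways
    through them.  Calpha fluctuation correlations are turned into edge
    weights d = -log|Corr| on a graph gated by persistent side-chain
    contacts; sphere-defined source and sink regions, per-subunit
    weighted shortest paths, source-sink restricted betweenness and a
    near-optimal-path centrality index locate the routes along which
    motion propagates, and wild-type versus mutant runs are compared by
    average path length.  A Gaussian bead-spring generator with
    analytically known correlation structure provides synthetic
    tetrameric trajectories for validation.
License: MIT + file LICENSE
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
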