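Package: pacsmsm
Title: Adaptive-Seeding Sampling and Markov State Model Analysis of Lipase Lid Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying slow conformational transitions with the
    parallel cascade selection (PaCS) adaptive-sampling protocol followed by
    Markov state model (MSM) analysis. Provides a two-dimensional Langevin
    engine with multi-well collective-variable landscapes emulating the
    closed/semiopen/open lid states of a lipase in water versus at a
    water-lipid interface, an engine-agnostic PaCS driver, microstate
    clustering and reversible transition-matrix estimation with implied
    timescales and free-energy landscapes, PCCA+ coarse-graining, mean
    first-passage times, transition-path-theory committors and flux networks,
    and macrostate-weighted residue contact / hydrogen-bond / salt-bridge
    statistics, including a crystal-structure geometry survey for PDB files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    bio3d,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
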