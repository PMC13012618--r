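Package: allonet
Title: Dynamic Network and Free-Energy Analysis of Molecular Dynamics
    Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for allosteric signalling in protein
    molecular-dynamics trajectories. Provides structure and trajectory
    input/output (PDB, GRO, DCD), atom selection and least-squares
    superposition, conformational order parameters (subdomain torsion
    angles, dihedrals, group distances, antiparallel beta-sheet content)
    and principal component analysis, typed inter-residue contact
    fingerprinting with differential comparison, dynamic correlation
    networks with generalized-correlation edge weights, optimal and
    suboptimal allosteric pathway tracing, Louvain community detection
    with betweenness centrality, and weighted-histogram (WHAM)
    reconstruction of free-energy profiles from umbrella-sampling time
    series with autocorrelation-aware bootstrap errors. Includes
    synthetic-data generators with machine-readable ground truth so every
    stage can be validated without external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
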