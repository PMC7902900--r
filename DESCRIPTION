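Package: trajan
Title: Trajectory Analysis of Protein Conformations, Energetics and
    Allosteric Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis of molecular dynamics trajectories of
    proteins and protein complexes: structure superposition (Kabsch), RMSD and
    RMSF profiles, inter-atomic geometry and contact/salt-bridge persistence,
    Shrake-Rupley solvent-accessible surface area, two-dimensional potentials
    of mean force over collective variables with basin segmentation,
    average-linkage conformational clustering with representative structures,
    MM/PBSA binding free-energy estimation with a finite-difference
    Poisson-Boltzmann solver and per-residue decomposition, and dynamic
    cross-correlation network analysis (persistence-gated networks, community
    detection by divisive edge betweenness, optimal and suboptimal allosteric
    paths).  A synthetic-trajectory generator with exact ground truth supports
    verification of every stage at desk scale.  Reads and writes multi-model
    PDB and binary DCD trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    graphics,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
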