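Package: fuzzytraj
Title: Trajectory and Sequence Analysis of Fuzzy Activation
    Domain-Coactivator Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of
    intrinsically disordered transcriptional activation domains bound to
    coactivator surfaces ("fuzzy" complexes). Reads multi-model PDB and
    CHARMM/NAMD DCD trajectories, computes pocket-occupancy distances and
    switch-like binding-state classifications, helix-orientation angles,
    Kabsch superposition with RMSD/RMSF profiles, DSSP-style per-frame
    secondary-structure timelines and helical-occupancy statistics, a
    simplified per-residue decomposition of intermolecular van der Waals
    and screened electrostatic interaction energies, three-coordinate
    phase-space densities with placement of reference NMR models, and a
    Lifson-Roig helix-coil model linking sequence-encoded helical
    propensity to transactivation potential. A synthetic-trajectory
    generator with ground-truth labels makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
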