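Package: metaldyn
Title: Reactivity Descriptors and Conformational State Analysis for
    Metal Complex-Protein Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising small metal complexes as enzyme
    substrates from desk-scale inputs: conceptual-DFT reactivity
    descriptors and second-order orbital stabilization energies from
    frontier-orbital data, a unit-cell similarity index and energy
    framework aggregation for crystal structures, trajectory deviation
    metrics (coordinate and distance RMSD, per-residue fluctuations,
    interdomain centre-of-mass distances), PCA/LDA collective-variable
    projection, Gaussian-mixture free-energy landscapes with
    inflection-based core-state extraction and state populations,
    ligand-protein linear interaction energies from point-charge Coulomb
    and Lennard-Jones terms, and per-residue electric fields projected
    onto a catalytic bond. Includes a synthetic-system generator
    (Brownian dynamics on multi-well potentials, metastable bead-model
    trajectories with known state weights) so the full pipeline is
    testable without external simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
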