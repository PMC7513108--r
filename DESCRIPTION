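Package: confent
Title: Configurational Entropy and Free-Energy Ranking of Protein
    Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding which conformation of a protein wins once
    configurational entropy is taken into account. Estimates per-residue
    partial entropies from torsion-angle ensembles by a marginal-entropy /
    adjacent-mutual-information decomposition, combines them with
    intramolecular enthalpy and solvation free-energy into cost functions,
    Boltzmann-ranks competing conformations, and selects the minimal subset
    of states that carries essentially all equilibrium weight. Includes
    structure characterization (Kabsch RMSD, UPGMA deduplication of decoy
    sets, C-alpha contact maps, radius of gyration, Shrake-Rupley solvent
    accessible surface area, simplified secondary structure), an
    internal-coordinate chain builder, and synthetic-ensemble generators
    with analytic entropies for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
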