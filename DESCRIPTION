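Package: hairyMD
Title: Coarse-Grained Molecular Dynamics of Adsorption on Ligand-Tethered Nanoparticles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bead-spring simulations of polymer-grafted ("hairy") nanoparticles
    and planar brushes immersed in an explicit fluid of spherical particles.
    Provides system builders for spherical and planar tethered layers (flexible
    or rigid ligands), a shifted-force Lennard-Jones force field with harmonic
    bonds, a velocity-Verlet NVT/NVE engine with a Nose-Hoover thermostat and
    hard walls, and estimators for excess adsorption isotherms, corona and
    brush thickness, radial and planar density profiles, peak structure, and
    corona asymmetry.  Includes analytic-profile fixtures so every estimator is
    testable without running dynamics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
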