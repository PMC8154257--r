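Package: denscomp
Title: Electron-Density Complementarity Scoring of Protein-Ligand Binding Poses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Evaluates and ranks protein-ligand binding poses by the
    complementarity of their promolecular electron densities. Molecular
    densities are built from spherically averaged Slater-type atomic
    contributions, sampled on a 0.1 Angstrom grid in the intermolecular
    region; at every point where the ligand and receptor clouds overlap the
    toolkit records the highest-contributing atom pair, their distance sum
    (SUMDLE) and a normalised log-density, and fits the linear
    complementarity law ln(rho_ligand * rho_enzyme) + rhoN = b + a * SUMDLE.
    Contact regions are resolved by single-linkage friends-of-friends
    clustering at the grid spacing, pose similarity by Hungarian
    symmetry-corrected RMSD, and docked poses are classified and ranked
    against a reference envelope of slope coefficients. Synthetic
    single-exponent fixtures with analytically known coefficients are
    included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
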