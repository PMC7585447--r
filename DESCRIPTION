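Package: foldmc
Title: All-Atom Torsion-Space Monte Carlo Sampling of Peptide Folding
    Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Metropolis Monte Carlo sampling of peptide conformations in
    torsion space with an AMBER-style intramolecular force field and a
    generalized Born + solvent-accessible-surface-area implicit solvent
    model.  Moves are Gaussian single-dihedral pivots, endpoint-constrained
    concerted (crankshaft) segment moves, and small whole-molecule rigid
    rotations, so bond lengths are never perturbed.  Includes a folding
    landscape analysis suite built on the fraction of native contacts Q:
    potential of mean force profiles, free-energy minima and barriers,
    folding temperatures, ensemble contact maps, per-residue stability,
    phi-values, heat capacity, Kabsch RMSD and hydrogen-bond distances,
    together with synthetic peptide generators so everything can be
    exercised without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
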