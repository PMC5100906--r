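Package: metawham
Title: Collective Variables, Umbrella Sampling/WHAM and Well-Tempered
    Metadynamics for Protein Conformational Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Geometric collective variables for helix-packing conformational
    change in nuclear-receptor ligand binding domains (difference RMSD to two
    reference states, rational-switching-function contact numbers, alpha-helix
    RMSD, helix crossing angles, side-chain function-group contacts and
    pi-cation criteria), together with the free-energy machinery built on
    them: umbrella sampling with weighted-histogram (WHAM) unbiasing and
    bootstrap errors, well-tempered metadynamics with hill deposition, wall
    biases, free-energy-surface reconstruction and convergence diagnostics,
    plus trajectory statistics (RMSD/RMSF, histogram PMFs, block-averaged
    dynamic cross-correlation networks, GROMOS conformational clustering,
    dihedral PCA). A seeded overdamped Langevin engine on analytic potentials
    and synthetic structure/trajectory generators provide exactly solvable
    inputs for verifying every method at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
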