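Package: detscreen
Title: Computational Detergent Screening for Membrane Protein Solubilization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory post-processing toolkit for computational detergent
    screening of membrane proteins. Scores detergents on two axes: membrane
    invasion (fraction of detergent molecules in heavy-atom contact with
    lipids within a periodic-boundary cutoff) and protein structural
    stabilization (per-residue RMSF after Kabsch superposition, differenced
    against a membrane-equilibrated reference profile), plus head/tail
    regioselectivity contact maps and a rank-sum combination that nominates
    candidate solubilizing detergents. Includes seeded toy-dynamics
    generators (Metropolis slab partitioning, Ornstein-Uhlenbeck residue
    fluctuations, propensity-driven head/tail placement) with closed-form
    expectations, readers and writers for multi-model PDB, GRO, and an
    extended-XYZ dialect, and cell-list neighbor searching under the minimum
    image convention.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
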