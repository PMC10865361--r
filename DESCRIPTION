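Package: ccfibril
Title: Trajectory Analysis of Self-Assembled Coiled-Coil Peptide Fibrils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics trajectories of
    self-assembling coiled-coil peptide hydrogels. Builds a virtual bead
    chain through the coiled-coil core and estimates fibril persistence
    length from orientation correlations; detects ammonium-carboxylate
    salt bridges under periodic boundaries and identifies oligomer chains
    (including circular fibrils), their size distributions and interaction
    lifetimes; computes radially resolved water density and local
    self-diffusion via FFT-based velocity autocorrelation and Green-Kubo
    integration; and provides closed-form hydrogel calculators (mesh size
    from the plateau modulus, loss tangent, cylindrical solvation-shell
    water retention, counterion bookkeeping). A synthetic-data module
    generates worm-like chains, Ornstein-Uhlenbeck velocity processes,
    planted salt-bridge assemblies, two-state interaction kinetics and
    solvated-cylinder particle fields with known ground truth, so every
    stage is testable without running molecular dynamics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
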