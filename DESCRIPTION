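Package: vgnp
Title: Virtual Gold Nanoparticle Surfaces and Nanohydrophobicity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds atomistic virtual gold nanoparticles (vGNPs) from a core
    diameter and a surface-ligand composition, identifies their
    solvent-accessible (Connolly) surface on a 3D grid with a water-sized
    probe, scores every surface point with a distance-weighted molecular
    lipophilicity potential based on atomic logP contributions, aggregates
    the surface into the logG/R nanohydrophobicity statistic, and converts
    logG/R into a predicted octanol-water partition coefficient (nanologP)
    through a linear calibration.  Includes calibration fitting, regression
    metrics, k-fold cross-validation, a ligand-weighted-average logP
    baseline, and synthetic particle-library generators for end-to-end
    testing.  Ligand parsing, seeded 3D embedding and Wildman-Crippen
    atomic contributions are obtained from RDKit through a bundled Python
    bridge.
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
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with rdkit, available as 'python' on
    the PATH (configurable via options(vgnp.python = ...)).
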