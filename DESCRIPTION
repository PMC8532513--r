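Package: gemevo
Title: Pan-Genome Metabolic Models, Trait Evolution and Evolution-Informed
    Essential-Gene Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative toolkit connecting genome evolution to metabolic
    traits. Derives species-specific genome-scale metabolic models (ssGEMs)
    from a pan-model and a gene existence matrix using boolean
    gene-protein-reaction (GPR) logic with complex/isozyme semantics,
    restores growth by minimal gap-filling, and simulates substrate
    utilization and gene essentiality by flux balance analysis.  Adds
    enzyme-constrained models with a shared protein pool for flux control
    coefficient analysis and kcat scans, trait gain/loss classification
    against ancestral-state posteriors, mechanistic attribution of trait
    losses (including downstream-pathway gaps), Alien-Index screening for
    horizontal gene transfer, residue conservation and spatial clustering of
    selected sites on protein structures, and sequence/evolution features
    for essential-gene classification.  Ships a synthetic-data module that
    generates every pipeline input with planted, recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    bio3d,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
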