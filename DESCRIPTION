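Package: decoyforest
Title: Random-Forest Scoring of Protein-Protein Docking Decoys
Version: 0.1.0
Authors@R:
    person("decoyforest", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Assessment and machine-learning rescoring of protein-protein
    docking decoys. Labels decoys by the CAPRI quality criteria (fraction of
    native contacts, ligand RMSD, interface RMSD), screens clash outliers,
    computes consensus contact-frequency (CONSRANK-style) scores, contact-class
    counts, buried surface area and non-interacting surface composition,
    ingests external per-decoy scoring-function tables, builds balanced and
    capped-unbalanced training datasets with target-level splits, and trains a
    class-weighted random-forest classifier with importance-driven forward
    feature selection. Includes a seeded synthetic decoy/feature generator for
    fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
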