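Package: pocketvote
Title: Ligand-Binding-Site Prediction from Per-Residue Structure
    Embeddings with Ensemble Voting and Point-Cloud Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts small-molecule binding sites on protein structures
    from per-residue embeddings. Residues are classified as ligand-binding
    by a balanced-bootstrap ensemble of gradient-boosted decision trees
    under a unanimous-vote rule; predicted residues are converted to site
    centres by annotating a shell lattice around the protein, keeping
    points near three or more predicted residues, and clustering them with
    a multiplicity-weighted DBSCAN. Includes solvent-accessibility
    filtering, Kabsch superposition and RMSD, the DCA/DCC/F1/MCC
    evaluation metrics, multi-structure consensus voting across
    conformers, and a synthetic fixture generator (pocket-bearing
    backbones, planted-signal embeddings, RMSD-targeted conformers) so the
    full pipeline can be exercised and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
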