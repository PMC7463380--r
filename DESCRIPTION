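Package: dtigist
Title: Drug-Target Interaction Prediction from PSSM Texture Descriptors
    and Rotation Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-target interactions by combining evolutionary
    information from protein position-specific scoring matrices (PSSMs)
    with drug substructure fingerprints. Each protein PSSM is treated as a
    two-dimensional image and summarised by a 512-dimensional GIST texture
    descriptor computed from a bank of 32 Gabor filters (4 scales by 8
    orientations) averaged over a 4x4 spatial grid. The 512 protein values
    are concatenated with 881-bit PubChem-style substructure fingerprints
    and drug-target pairs are classified with a rotation forest: an
    ensemble of decision trees, each trained on features rotated by a
    block-diagonal matrix of per-subset principal-component coefficients.
    Includes a PSI-BLAST ASCII PSSM parser, balanced negative sampling on
    bipartite interaction networks, stratified k-fold cross-validation
    with accuracy, precision, sensitivity, MCC, AUC and AUPR, and a
    synthetic-data generator with a planted, tunable interaction signal
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rpart,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
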