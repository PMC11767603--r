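Package: mcfdti
Title: Multi-Scale Convolutional Local-Global Feature Fusion for
    Drug-Target Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Binary drug-target interaction (DTI) classification from raw
    SMILES strings and protein sequences.  Drugs are encoded by two parallel
    multi-scale 1-D convolutional branches; targets by a parallel pair of a
    multi-scale convolutional path (local features) and a transformer encoder
    over byte-pair-encoded subwords (global features).  The streams are
    crossed by a shared attention mechanism and a biased feature interaction
    module, then selected and recalibrated by a channel-softmax selective
    fusion module with squeeze-and-excitation gating, and classified by a
    fully connected head.  Includes a Davis-benchmark-style loader with
    Kd-threshold binarization and balanced negative sampling, brute-force
    verified ranking metrics (AUROC, AUPR), a stratified k-fold
    cross-validation harness, and a seeded synthetic-data generator with a
    plantable conjunctive motif interaction rule.  All network layers and the
    Adam-trained forward/backward passes are implemented in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    seqinr,
    stats,
    utils,
    tools,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
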