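Package: lysgan
Title: Multi-Class Prediction of Lysine Post-Translational Modification
    Sites with GAN-Based Class Balancing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for multi-class prediction of lysine
    post-translational modification (PTM) sites from protein sequence.
    Extracts 17-residue lysine-centered peptide fragments from FASTA plus
    site annotations, removes redundant fragments, encodes each fragment
    with eight sequence schemes (AAindex physicochemical profiles, CKSAAP,
    position weight matrix, reduced alphabet, packing-density amyloidogenicity,
    binary one-hot, parallel- and series-correlation pseudo amino acid
    composition) plus a 19-channel structural block, screens features by
    Pearson correlation, balances the classes with a conditional
    (Wasserstein) generative adversarial network trained on the feature
    matrix, and classifies with a random forest evaluated by stratified
    cross-validation and an independent split using accuracy, multiclass
    Matthews correlation, confusion entropy, per-class sensitivity,
    specificity, AUC, DeLong AUC comparisons and scheme-grouped feature
    importance. Includes a seeded synthetic-fixture generator so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    pROC,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
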