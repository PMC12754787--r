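Package: ireseek
Title: Structure-Informed Deep Learning Identification of IRES Elements in
    Circular RNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A dual-branch classifier for internal ribosome entry sites
    (IRES) in circular RNA. A convolutional front-end followed by
    transformer blocks models the nucleotide sequence, while graph
    convolutional networks over base-pair probability (BPP) and base-pair
    motif energy (BPE) matrices model secondary structure; the two feature
    streams are fused by a multilayer perceptron. Class imbalance is
    handled by training one model on an oversampled and one on an
    undersampled dataset and soft-voting their predicted probabilities.
    Includes a simplified McCaskill-style partition function for built-in
    base-pair probabilities, adapters for ViennaRNA dot-plot and plain
    matrix files, a synthetic benchmark generator with planted AU-rich
    motifs and hairpins, the full metric suite (accuracy, precision,
    recall, F1, Matthews correlation coefficient, AUROC), and ablation /
    hyperparameter grid drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
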