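Package: mirtransfer
Title: Cross-Species Transfer Learning for miRNA-Target Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for predicting miRNA-mRNA target interactions (MTIs)
    in species with limited training data. Implements duplex scoring and seed-type
    classification of miRNA:target-site pairs, seed-constrained generation of
    synthetic negative interactions, miRNA-stratified dataset splitting, transfer
    learning for tabular MTI features with feed-forward neural networks (layer
    freezing) and gradient-boosted trees (boosting continuation), evaluation
    harnesses for intra-species, cross-species and transfer-curve experiments,
    and TransferSHAP, a Shapley-value based measure of per-feature importance of
    the transfer step itself. A synthetic multi-species data generator with a
    controllable domain shift makes the whole pipeline testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mclust,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
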