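Package: secretrain
Title: Semi-Supervised Prediction of Blood-Secretory Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts which human proteins are secreted into the bloodstream
    from their amino-acid sequences. Combines a physicochemical and
    sequence-derived descriptor engine, unsupervised feature selection by
    differential evolution with a k-means silhouette fitness, a dual-pathway
    convolutional/bidirectional-LSTM classifier, and a biologically
    constrained self-training loop that expands scarce labels with
    high-confidence pseudo-labels while keeping the predicted secretory
    fraction inside a prior band. Includes rule-based negative-set filtering,
    secretion-marker scanning (ER-retention and dibasic cleavage motifs),
    evaluation metrics, and a synthetic sequence generator with planted
    secretion cues for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
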