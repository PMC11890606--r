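Package: tweetformer
Title: Additive-Attention Transformer Classifier for Short Social-Media Texts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end classifier for short, noisy social-media texts such as
    adverse-drug-reaction tweets. Builds a hybrid word representation that
    concatenates a trainable 300-dimensional word vector (with character
    n-gram decomposition for out-of-vocabulary words) to a fixed random
    positional vector, passes it through a two-layer bidirectional LSTM
    context encoder, and feeds the result to a linear-complexity additive
    attention transformer encoder with global query and context-aware key
    summarization. Includes a deterministic tweet-normalization pipeline,
    a seeded synthetic-corpus generator for reproducible experiments,
    positive-class and micro-averaged F1 evaluation utilities, and a small
    command-line interface. All forward and backward passes are implemented
    in R and C++; no external deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    stringi,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
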