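Package: synthcc
Title: Synthetic Chief-Complaint Generation from Structured Emergency
    Department Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Conditional natural-language generation for emergency department
    (ED) visit records. A feedforward record encoder compresses the sparse
    binary encoding of a visit's discrete variables (age group, gender,
    diagnosis codes, and similar) into the initial state of a single-layer
    LSTM decoder that emits a free-text chief complaint one token at a time.
    The package implements the full pipeline: schema definition and sparse
    vectorization, text preprocessing and vocabulary construction, a
    synthetic-corpus simulator with planted statistical structure, end-to-end
    model training with autoencoder pretraining of the record encoder, greedy,
    temperature and beam-search decoding, variable-length n-gram and TF-IDF
    text-quality metrics, epidemiological validity checks (word-variable
    contingency tables, risk and odds ratios, a GRU diagnosis classifier),
    and an embedding-based audit for residual personal names in generated
    text.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
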