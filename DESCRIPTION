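Package: foldvec
Title: Structure Embeddings for Scalable Protein Similarity Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for multi-scale protein structure similarity search with
    fixed-length embeddings. Reads PDB/mmCIF chains as CA traces, computes
    TM-scores by Kabsch superposition with an iterative fragment-seed search,
    generates hierarchical synthetic fold benchmarks, trains a twin
    transformer aggregator so that embedding cosine similarity approximates
    the TM-score, evaluates retrieval with sensitivity-to-first-false-positive
    and precision-recall statistics, and serves embeddings through an exact
    cosine k-NN reference search plus a Hierarchical Navigable Small World
    (HNSW) approximate index.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
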