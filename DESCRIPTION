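Package: ncpmd
Title: Network Consistency Projection for Microbe-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores candidate microbe-disease associations by projecting a
    Gaussian interaction profile (GIP) kernel microbe-similarity network and an
    integrated disease-similarity network (symptom-based TF-IDF/cosine
    similarity where available, GIP kernel similarity otherwise) onto the known
    bipartite association network. The method is parameter-free: both
    projections are combined and normalised by similarity-vector lengths.
    Includes leave-one-out and k-fold cross-validation with per-trial kernel
    recomputation, rank-based ROC/AUC, a planted-partition synthetic network
    generator for end-to-end testing, tidy accessors for every result type,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
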