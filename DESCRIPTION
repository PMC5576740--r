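Package: nmflp
Title: Link Prediction in Attributed Networks by Joint Non-Negative
    Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts missing links in undirected simple networks by jointly
    factorizing the adjacency matrix and an optional node-attribute matrix
    into a shared non-negative latent space with a consensus embedding,
    optimized by multiplicative update rules. Provides the classical
    neighborhood similarity indices (common neighbours, Salton, Jaccard,
    Sorensen, hub promoted/depressed, Leicht-Holme-Newman, preferential
    attachment) as baselines, a train/probe evaluation protocol with
    sampling and exact AUC and precision-at-L, a k-fold cross-validation
    benchmark harness, and a stochastic-block-model generator with planted
    attributes for testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
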