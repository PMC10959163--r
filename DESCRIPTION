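Package: mdpgcn
Title: miRNA-Disease Association Prediction with Regular-Graph Convolutional
    Networks and Edge Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts miRNA-disease associations by recasting link prediction
    as transductive node classification. Each miRNA-disease pair becomes a
    node whose features concatenate integrated miRNA similarity (functional
    plus Gaussian interaction profile kernel) and integrated disease
    similarity (semantic plus kernel) rows. Nodes are wired into an exactly
    k-regular graph by a mutual k-nearest-neighbour rule with a deterministic
    regularity repair, and a graph convolutional network is trained on
    minibatches drawn by a degree-weighted random edge sampler with empirical
    bias-correcting normalization coefficients. Includes non-regular
    (k-means clique) and heterogeneous entity-graph contrast builders, four
    association-novelty evaluation regimes, repeated-experiment metrics with
    paired tests, case-study candidate ranking, and a synthetic planted-block
    data generator so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    methods,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
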