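Package: sigreach
Title: Interaction Probabilities in Probabilistic Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers per-interaction existence probabilities for a directed
    signaling network from end-to-end signal reachability. An exact
    xy-polynomial engine with path/cut collapsing computes two-terminal
    signal reachability between receptor (source) and reporter (target)
    genes; a genetic algorithm searches the space of edge-probability
    vectors globally; and a closed-form per-edge hill climber refines the
    result by coordinate descent, using the fact that reachability is
    affine in any single deferred edge probability. Empirical reachability
    is taken as the absolute Pearson correlation between source and target
    gene expression. Includes a synthetic network/instance generator and
    post-fit analytics (result quality, probability-spread entropy,
    between-condition distances, outstanding interactions and genes, and
    removal-based node centrality).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
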