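Package: linksliced
Title: Slice-Based Evaluation of Link Prediction on Biomedical Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for evaluating link prediction on biomedical
    graphs such as drug-target, protein-interaction and literature
    co-occurrence networks. Graphs are sliced into induction, train and test
    link sets either at random (preserving connectivity) or chronologically;
    negatives are sub-sampled at a 1:1 ratio; candidate links are scored with
    neighbourhood heuristics (Common Neighbours, Adamic-Adar, Jaccard, with
    bipartite modifications) and with random-walk node embeddings fed through
    a minimalist feed-forward predictor; rankings are evaluated with five
    metrics split into link-equality (AUROC, AUPR, precision at k) and
    node-equality (MAP, averaged R-precision) families, with a diagnostic for
    test links whose endpoints share no prior common neighbours. A stochastic
    block model generator with skewed edge timestamps makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
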