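Package: dtiwl
Title: Drug-Target Interaction Prediction from Enclosing Subgraphs with
    Palette Weisfeiler-Lehman Ordering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Link prediction on semi-bipartite drug-target interaction
    networks. Known interactions plus drug-drug and protein-protein
    similarity matrices are modelled as one weighted graph; for every
    candidate (drug, target) pair a K-vertex enclosing subgraph is
    extracted, vertex-ordered by a Palette Weisfeiler-Lehman colour
    refinement anchored on the pair, encoded as the upper triangle of its
    K x K adjacency matrix, and classified by a small fully-connected
    neural network. Includes reliability-ranked negative sampling,
    classical link-prediction heuristics (preferential attachment, common
    neighbours, Jaccard, Katz), a stratified cross-validation harness with
    AUROC/AUPR metrics, and a seeded generator of synthetic networks with
    planted guilt-by-association structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
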