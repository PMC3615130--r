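Package: netrobust
Title: Attack Robustness of Complex Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Quantifies the structural robustness of undirected networks under
    targeted vertex removal. Generates model networks with controlled degree
    distribution (Barabasi-Albert, growing random), clustering (Holme-Kim with
    calibrated triad formation) and degree assortativity (degree-preserving
    rewiring); attacks them by removing vertices ranked by degree, eigenvector,
    closeness or betweenness centrality -- simultaneously, sequentially with
    recalculation, or uniformly at random; and summarises the damage with the
    largest-component curve S(q), the Schneider R-index and the complementary
    V-index. Includes readers for edge-list and GML files so empirical networks
    (neural, protein-protein interaction, social) can be analysed the same way.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
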