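Package: orbcensus
Title: Orbit-Aware Quad and Triad Censuses for Sparse Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact per-node and per-edge four-node subgraph (quad) censuses
    for simple undirected graphs, separated into automorphism orbits and
    reported both as induced and non-induced counts, computed from a single
    degeneracy-oriented clique-listing scan plus exact linear systems
    relating non-induced to induced frequencies. Also provides the
    node-orbit-aware triad census and the 16-class graph-level triad census
    for simple directed graphs, brute-force reference censuses, canonical
    orbit atlases, and seeded synthetic graph generators (small-world ring
    rewiring, neighborhood-biased preferential attachment, and G(n,p)).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
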