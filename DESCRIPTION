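Package: pathmult
Title: Shortest-Path Multiplicity Analysis for Complex Networks
Version: 0.2.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Counts shortest paths (geodesics) between all node pairs of an
    undirected network with an exact matrix-power algorithm and an independent
    breadth-first-search oracle, and aggregates the counts into per-node and
    network-level path-multiplicity indices. Includes nonlinear least-squares
    power-law fitting of path-multiplicity and degree distributions with a
    coefficient-of-determination goodness of fit, generators for
    Erdos-Renyi, Newman-Watts, Barabasi-Albert and clustered Barabasi-Albert
    reference models matched to a target network by size and edge density,
    and classical network metrics (assortativity, clustering, average
    shortest path length, centralities) for cross-metric comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
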