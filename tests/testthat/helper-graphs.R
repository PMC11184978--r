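# Shared fixture helpers. All randomness goes through an explicit seed so
# every run of the suite sees the same graphs.

# a connected ER draw (re-drawn until connected); p = NULL picks a density
# high enough that connected samples are not vanishingly rare at size n
random_connected_er <- function(n, p = NULL) {
  if (is.null(p)) {
    lo <- min(2.5 / n, 0.8)
    p <- stats::runif(1, lo, min(lo + 0.25, 1))
  }
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) return(g)
  }
}

# brute-force geodesic count between two nodes via igraph path enumeration;
# independent of both package engines
count_geodesics_igraph <- function(g, from, to) {
  length(igraph::all_shortest_paths(g, from = from, to = to)$vpaths)
}

# write lines to a temp file and return its path
tmp_edge_file <- function(lines) {
  tf <- tempfile(fileext = ".txt")
  writeLines(lines, tf)
  tf
}
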