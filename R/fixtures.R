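#' Deterministic toy-topology fixtures
#'
#' Named constructions of the classical topologies used throughout the
#' examples, tests and documentation. Every fixture regenerates
#' bit-identically: no randomness is involved.
#'
#' Available fixtures:
#' - `"tree"`: rooted `children`-ary tree on `n` nodes (unique geodesics,
#'   so Phi = 1).
#' - `"star"`: star on `n` nodes, centre first (Phi = 1).
#' - `"complete"`: complete graph on `n` nodes (Phi = 1).
#' - `"ring"`: circular lattice, each node joined to `nei` nearest
#'   neighbours per side (default 2).
#' - `"grid"`: rectangular 4-neighbour lattice with dimensions `dims`
#'   (default `c(4, 4)`), no periodic boundary. Corner-to-corner pairs have
#'   `choose(a + b - 2, a - 1)` geodesics of length `a + b - 2`.
#' - `"hypercube"`: `d`-dimensional hypercube (set `n` to the dimension,
#'   default 3). Antipodal pairs have `d!` geodesics.
#' - `"fig1_union"`: the 6-node, 8-edge graph formed by the union of the
#'   four length-3 geodesics v1-v2-v3-v6, v1-v2-v5-v6, v1-v4-v3-v6 and
#'   v1-v4-v5-v6, the worked example for a pair (v1, v6) with 4 geodesics.
#'
#' @param name fixture identifier (see above).
#' @param n size parameter: node count, or the dimension for
#'   `"hypercube"`; ignored for `"fig1_union"`.
#' @param dims integer dimensions for `"grid"`.
#' @param children branching factor for `"tree"`.
#' @param nei ring neighbours per side for `"ring"`.
#' @return A simple undirected `igraph` graph with named vertices.
#' @examples
#' phi_index(path_hesitation(make_fixture("complete", n = 10)))  # 1
#' g <- make_fixture("grid", dims = c(4, 4))
#' path_hesitation(g)$H["1", "16"]  # choose(6, 3) = 20
#' @export
make_fixture <- function(name, n = NULL, dims = c(4L, 4L),
                         children = 2L, nei = 2L) {
  known <- c("tree", "star", "complete", "ring", "grid", "hypercube",
             "fig1_union")
  if (!is.character(name) || length(name) != 1L || !(name %in% known)) {
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(known, collapse = ", "))
  }
  g <- switch(name,
    tree = igraph::make_tree(if (is.null(n)) 15L else n, children = children,
                             mode = "undirected"),
    star = igraph::make_star(if (is.null(n)) 10L else n, mode = "undirected"),
    complete = igraph::make_full_graph(if (is.null(n)) 10L else n),
    ring = igraph::make_lattice(length = if (is.null(n)) 12L else n,
                                dim = 1, nei = nei, periodic = TRUE),
    grid = igraph::make_lattice(dims),
    hypercube = igraph::make_lattice(rep(2L, if (is.null(n)) 3L else n)),
    fig1_union = {
      el <- matrix(c("v1", "v2",  "v2", "v3",  "v3", "v6",  "v2", "v5",
                     "v5", "v6",  "v1", "v4",  "v4", "v3",  "v4", "v5"),
                   ncol = 2L, byrow = TRUE)
      igraph::graph_from_edgelist(el, directed = FALSE)
    })
  if (is.null(igraph::vertex_attr(g, "name"))) {
    g <- igraph::set_vertex_attr(g, "name",
                                 value = as.character(seq_len(igraph::vcount(g))))
  }
  g
}
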