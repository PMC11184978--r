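#' Reference random-graph models
#'
#' Generators for the four null models used to benchmark path multiplicity:
#' Erdos-Renyi (ER) random graphs, Newman-Watts (NW) small-world graphs,
#' Barabasi-Albert (BA) scale-free graphs, and clustered Barabasi-Albert
#' (CBA) graphs with a triad-formation step. All outputs are simple
#' undirected graphs on exactly `n` vertices. With the same arguments and
#' `seed`, the edge set is reproduced exactly.
#'
#' - **ER**: each of the `n(n-1)/2` pairs is an edge independently with
#'   probability `p`.
#' - **NW**: a circular lattice in which every node is joined to its
#'   `k_ring` nearest neighbours on each side, plus random shortcut edges —
#'   one candidate shortcut per lattice edge with probability `p_tilde`, no
#'   edges removed (shortcut *addition*, the Newman-Watts variant of the
#'   small-world model).
#' - **BA**: growth from a complete seed graph on `m0` nodes; each arriving
#'   node attaches `m` edges to distinct existing nodes sampled without
#'   replacement with probability proportional to current degree.
#' - **CBA**: BA plus triad formation — after each preferential attachment
#'   to a target node, `ms` further edges join the new node to randomly
#'   chosen neighbours of that target (raising clustering); if fewer
#'   eligible neighbours remain, it connects to all of them.
#'
#' @param model one of `"er"`, `"nw"`, `"ba"`, `"cba"`.
#' @param n number of nodes.
#' @param p ER edge probability, in `[0, 1]`.
#' @param k_ring NW lattice neighbours per side (so base-ring degree is
#'   `2 * k_ring`).
#' @param p_tilde NW shortcut probability per lattice edge, in `[0, 1]`.
#' @param m edges attached per arriving node (BA/CBA), `1 <= m <= m0 < n`.
#' @param m0 seed-clique size, default `m`.
#' @param ms triad-formation edges per preferentially attached target node
#'   (CBA), `0 <= ms <= m`.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first so the draw is reproducible.
#' @return A simple undirected `igraph` graph with `n` vertices.
#' @examples
#' g <- sample_model("ba", n = 100, m = 3, seed = 1)
#' igraph::ecount(g)  # choose(3, 2) + 3 * 97
#' @export
sample_model <- function(model = c("er", "nw", "ba", "cba"), n,
                         p = NULL, k_ring = 2L, p_tilde = 0.1,
                         m = 3L, m0 = m, ms = 1L, seed = NULL) {
  model <- match.arg(model)
  switch(model,
         er  = sample_er(n, p, seed = seed),
         nw  = sample_nw(n, k_ring, p_tilde, seed = seed),
         ba  = sample_ba(n, m, m0, seed = seed),
         cba = sample_cba(n, m, ms, m0, seed = seed))
}

#' @rdname sample_model
#' @export
sample_er <- function(n, p, seed = NULL) {
  if (is.null(p) || p < 0 || p > 1) stop("ER model needs edge probability p in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  igraph::sample_gnp(n, p)
}

#' @rdname sample_model
#' @export
sample_nw <- function(n, k_ring = 2L, p_tilde = 0.1, seed = NULL) {
  if (k_ring < 1L || 2L * k_ring >= n) stop("need 1 <= k_ring < n/2")
  if (p_tilde < 0 || p_tilde > 1) stop("shortcut probability p_tilde must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::make_lattice(length = n, dim = 1, nei = k_ring, periodic = TRUE)
  n_short <- stats::rbinom(1L, igraph::ecount(g), p_tilde)
  if (n_short > 0L) {
    u <- sample.int(n, n_short, replace = TRUE)
    v <- sample.int(n, n_short, replace = TRUE)
    ok <- u != v
    if (any(ok)) {
      g <- igraph::add_edges(g, rbind(u[ok], v[ok]))
      g <- igraph::simplify(g)
    }
  }
  g
}

#' @rdname sample_model
#' @export
sample_ba <- function(n, m, m0 = m, seed = NULL) {
  grow_ba(n, m, m0, ms = 0L, seed = seed)
}

#' @rdname sample_model
#' @export
sample_cba <- function(n, m, ms = 1L, m0 = m, seed = NULL) {
  grow_ba(n, m, m0, ms = ms, seed = seed)
}

# Shared growth process. Preferential attachment is sampled without
# replacement, proportional to current degree, via a repeated-node urn.
# ms > 0 adds the triad-formation step after each attachment.
grow_ba <- function(n, m, m0, ms, seed = NULL) {
  if (m < 1L || m > m0 || m0 >= n) stop("need 1 <= m <= m0 < n")
  if (ms < 0L || ms > m) stop("need 0 <= ms <= m")
  if (!is.null(seed)) set.seed(seed)

  nbrs <- vector("list", n)
  for (i in seq_len(m0)) nbrs[[i]] <- setdiff(seq_len(m0), i)
  # urn: every node repeated once per unit of degree
  urn <- rep(seq_len(m0), each = m0 - 1L)

  for (v in seq.int(m0 + 1L, n)) {
    targets <- integer(0)
    while (length(targets) < m) {
      cand <- urn[sample.int(length(urn), 1L)]
      if (!(cand %in% targets)) targets <- c(targets, cand)
    }
    new_edges <- targets
    if (ms > 0L) {
      for (t in targets) {
        eligible <- setdiff(nbrs[[t]], c(v, new_edges))
        take <- min(ms, length(eligible))  # saturate: connect to all available
        if (take > 0L) {
          picked <- eligible[sample.int(length(eligible), take)]
          new_edges <- c(new_edges, picked)
        }
      }
    }
    for (w in new_edges) {
      nbrs[[w]] <- c(nbrs[[w]], v)
    }
    nbrs[[v]] <- new_edges
    urn <- c(urn, new_edges, rep(v, length(new_edges)))
  }

  el <- cbind(rep(seq_len(n), lengths(nbrs)), unlist(nbrs))
  el <- el[el[, 1L] < el[, 2L], , drop = FALSE]
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' Model graph matched to a target network by size and edge density
#'
#' Draws a reference model graph with the same number of nodes as `target`
#' and parameters chosen so the expected edge count matches the target's as
#' closely as the model's parameter granularity allows:
#' ER uses `p` equal to the target's edge density; BA rounds `m = W/N`;
#' CBA accounts for the ~`m * ms` extra triad edges per arriving node and
#' rounds `m = W / (N (1 + ms))`; NW takes `k_ring = floor(W/N)` lattice
#' neighbours per side and sets the shortcut probability to absorb the
#' remainder. Sparse ER/NW draws can come out disconnected; those are
#' re-drawn up to 100 times and the giant component of the final draw is
#' returned, so path-multiplicity indices are always defined.
#'
#' @param target a connected `igraph` graph with at least 10 nodes.
#' @param model one of `"er"`, `"nw"`, `"ba"`, `"cba"`.
#' @param seed optional integer seed for the draw.
#' @param ms triad edges per attached node when `model = "cba"`.
#' @return A connected simple undirected `igraph` graph.
#' @export
matched_reference <- function(target, model = c("er", "nw", "ba", "cba"),
                              seed = NULL, ms = 1L) {
  model <- match.arg(model)
  check_simple_undirected(target)
  n <- igraph::vcount(target)
  w <- igraph::ecount(target)
  if (n < 10L) stop("target must have at least 10 nodes")
  if (!igraph::is_connected(target)) stop("target must be connected")
  if (!is.null(seed)) set.seed(seed)

  draw <- switch(model,
    er = {
      p <- 2 * w / (n * (n - 1))
      function() igraph::sample_gnp(n, p)
    },
    nw = {
      k_ring <- floor(w / n)
      if (k_ring < 1L) {
        stop(sprintf(
          "target density unreachable by the NW model: minimum ring density is %.4g, target has %.4g",
          2 / (n - 1), 2 * w / (n * (n - 1))))
      }
      pt <- max(0, min(1, w / (n * k_ring) - 1))
      function() sample_nw(n, k_ring, pt)
    },
    ba = {
      m <- max(1L, as.integer(round(w / n)))
      function() sample_ba(n, m)
    },
    cba = {
      m <- max(1L, as.integer(round(w / (n * (1 + ms)))))
      if (ms > m) stop(sprintf(
        "target density unreachable by the CBA model with ms = %d (would need m = %d < ms)",
        ms, m))
      function() sample_cba(n, m, ms)
    })

  g <- draw()
  tries <- 1L
  while (!igraph::is_connected(g) && tries < 100L) {
    g <- draw()
    tries <- tries + 1L
  }
  if (!igraph::is_connected(g)) g <- giant_component(g)
  g
}
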