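#' Global topology metrics of a network
#'
#' One row of the classical metrics commonly set against path multiplicity:
#' size, mean degree, edge density, degree assortativity (Pearson
#' correlation of degrees across edge endpoints), clustering coefficient,
#' average shortest path length, and the path-multiplicity index Phi.
#' The geodesic lengths are reused from the path-multiplicity result rather
#' than recomputed, so `avg_path_length` and `phi` come from the same
#' all-pairs pass.
#'
#' @param g a connected, simple, undirected `igraph` graph.
#' @param ph optionally, a precomputed [path_hesitation] result for `g`.
#' @param clustering `"local"` (default) for the mean local clustering
#'   coefficient, with degree-<2 nodes contributing 0, or `"global"` for
#'   transitivity (triangle density). The paper-style comparison does not
#'   pin this down; the local mean is the common scatter-plot convention.
#' @return A one-row data frame with columns `N`, `W`, `mean_degree`,
#'   `p_edge`, `assortativity`, `clustering`, `avg_path_length`, `phi`.
#' @export
global_metrics <- function(g, ph = NULL, clustering = c("local", "global")) {
  clustering <- match.arg(clustering)
  check_simple_undirected(g)
  if (!igraph::is_connected(g)) stop("graph must be connected")
  if (is.null(ph)) ph <- path_hesitation(g)
  stopifnot(inherits(ph, "path_hesitation"), ph$n == igraph::vcount(g))
  n <- ph$n
  deg <- igraph::degree(g)
  cc <- if (clustering == "local") {
    mean(igraph::transitivity(g, type = "local", isolates = "zero"))
  } else {
    igraph::transitivity(g, type = "global")
  }
  data.frame(N = n,
             W = igraph::ecount(g),
             mean_degree = mean(deg),
             p_edge = mean(deg) / (n - 1),
             assortativity = igraph::assortativity_degree(g, directed = FALSE),
             clustering = cc,
             avg_path_length = mean(ph$L[upper.tri(ph$L)]),
             phi = ph$phi)
}

#' Per-node centrality table
#'
#' Degree centrality `d_i/(N-1)`, shortest-path betweenness normalised by
#' `(N-1)(N-2)/2`, and the per-node path-multiplicity degree, aligned with
#' the graph's vertex order.
#'
#' @inheritParams global_metrics
#' @return A data frame with columns `node`, `degree_centrality`,
#'   `betweenness`, `phd`, one row per vertex.
#' @export
node_centralities <- function(g, ph = NULL) {
  check_simple_undirected(g)
  if (!igraph::is_connected(g)) stop("graph must be connected")
  if (is.null(ph)) ph <- path_hesitation(g)
  n <- ph$n
  data.frame(node = vertex_labels(g),
             degree_centrality = igraph::degree(g) / (n - 1),
             betweenness = igraph::betweenness(g, directed = FALSE,
                                               normalized = TRUE),
             phd = ph$phd,
             row.names = NULL)
}

#' Betweenness recomputed from the geodesic-count matrices
#'
#' Pair dependencies assembled directly from the path-multiplicity result:
#' node v lies on a geodesic between s and t iff `L[s,v] + L[v,t] == L[s,t]`,
#' in which case the fraction of s-t geodesics through v is
#' `H[s,v] * H[v,t] / H[s,t]`. Summing over unordered pairs (s, t) excluding
#' v and normalising by `(N-1)(N-2)/2` gives the standard normalised
#' betweenness; agreement with the usual accumulation algorithm is a strong
#' consistency check on `H` and `L`.
#'
#' @param ph a [path_hesitation] result.
#' @return Named numeric vector of normalised betweenness values.
#' @export
betweenness_from_pha <- function(ph) {
  stopifnot(inherits(ph, "path_hesitation"))
  H <- ph$H; L <- ph$L; n <- ph$n
  b <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- outer(L[, v], L[v, ], "+") == L
    frac <- outer(H[, v], H[v, ]) / pmax(H, 1) * on_path
    frac[v, ] <- 0; frac[, v] <- 0
    b[v] <- sum(frac[upper.tri(frac)])
  }
  names(b) <- rownames(H)
  b / ((n - 1) * (n - 2) / 2)
}

#' Overlap between the top-k nodes of two centrality rankings
#'
#' Fraction of nodes shared by the top-k sets of two columns of a
#' [node_centralities()] table. Ties are broken deterministically by row
#' (node) index, so the result is reproducible.
#'
#' @param table a per-node table from [node_centralities()].
#' @param metric_a,metric_b column names to rank by.
#' @param k size of the head of each ranking, `k <= N`.
#' @return The overlap fraction in `[0, 1]`.
#' @export
top_k_overlap <- function(table, metric_a, metric_b, k) {
  for (m in c(metric_a, metric_b)) {
    if (!m %in% names(table)) {
      stop(sprintf("unknown metric '%s'; available: %s",
                   m, paste(setdiff(names(table), "node"), collapse = ", ")))
    }
  }
  if (k > nrow(table)) stop("k exceeds the number of nodes")
  top <- function(m) {
    ord <- order(-table[[m]], seq_len(nrow(table)))
    ord[seq_len(k)]
  }
  length(intersect(top(metric_a), top(metric_b))) / k
}

#' Correlation of the path-multiplicity index with global metrics
#'
#' Given global-metric rows for several networks (one per network),
#' correlates `phi` against each classical metric across networks. A metric
#' that is constant across the collection has an undefined correlation and
#' is reported as `NA` rather than raising an error.
#'
#' @param reports a data frame of rows from [global_metrics()] (at least 3),
#'   or a list of such rows to be bound together.
#' @param method `"pearson"` (scatter-plot annotation convention, default)
#'   or `"spearman"`.
#' @return A data frame with columns `metric` and `correlation`.
#' @export
metric_correlations <- function(reports, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.list(reports) && !is.data.frame(reports)) {
    reports <- do.call(rbind, reports)
  }
  if (nrow(reports) < 3L) stop("need at least 3 networks to correlate")
  metrics <- setdiff(names(reports), c("phi", "W"))
  corr <- vapply(metrics, function(m) {
    x <- reports[[m]]
    if (anyNA(x) || stats::sd(x) == 0 || stats::sd(reports$phi) == 0) {
      NA_real_
    } else {
      stats::cor(reports$phi, x, method = method)
    }
  }, numeric(1))
  data.frame(metric = metrics, correlation = unname(corr), row.names = NULL)
}
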