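#' All-pairs shortest-path counts and path-multiplicity indices
#'
#' Computes, for every unordered node pair of a connected undirected graph,
#' the geodesic length `l_ij` and the number of distinct geodesics `h_ij`
#' (the pair's path-multiplicity, here called the Path Hesitation Amount,
#' PHA), and aggregates them into the per-node Path Hesitation Degree
#'
#' \deqn{\tilde d_i = \frac{1}{N-1}\sum_{j\neq i} h_{ij}}
#'
#' and the network-level Path Hesitation Index
#'
#' \deqn{\Phi(G) = \frac{1}{N}\sum_i \tilde d_i
#'              = \frac{\sum_i\sum_{j\neq i} h_{ij}}{N(N-1)} \ge 1.}
#'
#' `method = "matrix"` uses the fast matrix-power scheme: starting from
#' `H = L = 0` and `k = 1`, each iteration masks the already-resolved pairs
#' (entrywise mask `T`, with the diagonal permanently excluded since
#' `h_ii = 0` by definition), accumulates `H <- H + T * A^k`, stamps `L` with
#' `k` on newly resolved pairs, and advances `A^k` by one multiplication —
#' `O(diameter * N^3)` overall. Walks of length equal to the graph distance
#' are exactly the geodesics, which is why the masked `A^k` entry is the
#' geodesic count. `method = "bfs"` is an independent per-source
#' breadth-first search that accumulates predecessor counts along the
#' shortest-path DAG; the two must agree exactly and the BFS route serves as
#' a verification oracle.
#'
#' Counts are held in doubles, which are exact integers up to 2^53; the
#' matrix engine stops with an error before any `A^k` product could exceed
#' that bound, so returned counts are always exact.
#'
#' @param g a connected, undirected, simple `igraph` graph with `N >= 2`
#'   vertices. Disconnected input is an error; extract the
#'   [giant_component()] first.
#' @param method `"matrix"` for the matrix-power algorithm (default) or
#'   `"bfs"` for the breadth-first-search oracle.
#' @return An object of class `"path_hesitation"`: a list with `H` (N x N
#'   symmetric matrix of geodesic counts, zero diagonal), `L` (N x N matrix
#'   of geodesic lengths), `phd` (named per-node vector), `phi` (scalar
#'   index), `n`, `diameter`, `method` and `call`.
#' @examples
#' g <- make_fixture("fig1_union")
#' ph <- path_hesitation(g)
#' ph$H["v1", "v6"]   # 4 geodesics
#' ph$L["v1", "v6"]   # of length 3
#' phi_index(ph)
#' @seealso [pha_distribution()], [phd_vector()], [phi_index()],
#'   [pha_matrix_fast()], [pha_matrix_oracle()]
#' @export
path_hesitation <- function(g, method = c("matrix", "bfs")) {
  method <- match.arg(method)
  check_simple_undirected(g)
  n <- igraph::vcount(g)
  if (n < 2L) stop("path multiplicity needs at least 2 nodes")
  if (!igraph::is_connected(g)) {
    stop("graph is disconnected: extract the giant connected component ",
         "first (see giant_component())")
  }
  res <- switch(method,
                matrix = pha_engine_matrix(adjacency_dense(g)),
                bfs    = pha_engine_bfs(g))
  nm <- vertex_labels(g)
  dimnames(res$H) <- dimnames(res$L) <- list(nm, nm)
  phd <- rowSums(res$H) / (n - 1)
  names(phd) <- nm
  structure(list(H = res$H, L = res$L,
                 phd = phd, phi = mean(phd),
                 n = n, diameter = res$diameter,
                 method = method, call = match.call()),
            class = "path_hesitation")
}

#' @rdname path_hesitation
#' @export
pha_matrix_fast <- function(g) path_hesitation(g, method = "matrix")

#' @rdname path_hesitation
#' @export
pha_matrix_oracle <- function(g) path_hesitation(g, method = "bfs")

# Matrix-power engine. A is a dense 0/1 adjacency matrix of a connected
# graph. The mask excludes the diagonal permanently (h_ii = 0); without
# that exclusion the growing diagonal of A^k (closed walks) would pollute H.
pha_engine_matrix <- function(A) {
  n <- nrow(A)
  H <- matrix(0, n, n)
  L <- matrix(0, n, n)
  off <- !diag(n)
  Ak <- A
  k <- 1L
  repeat {
    Tm <- off & (H == 0)
    contrib <- Ak * Tm
    newly <- contrib != 0
    H <- H + contrib
    L[newly] <- k
    if (all(H[off] != 0)) break
    if (k >= n - 1L) {
      stop("unresolved node pairs at k = N - 1: graph is disconnected; ",
           "extract the giant connected component first")
    }
    # next product's entries are bounded by n * max(Ak); stay exact in doubles
    if (n * max(Ak) >= 2^53) {
      stop("shortest-path counts exceed the exact integer range of doubles (2^53)")
    }
    Ak <- Ak %*% A
    k <- k + 1L
  }
  list(H = H, L = L, diameter = k)
}

# BFS engine: per-source geodesic counting via predecessor accumulation.
pha_engine_bfs <- function(g) {
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  n <- length(adj)
  H <- matrix(0, n, n)
  L <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    sigma <- numeric(n)
    dist[s] <- 0L
    sigma[s] <- 1
    queue <- integer(n)
    queue[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      dv <- dist[v]
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dv + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dv + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    if (any(dist < 0L)) {
      stop("graph is disconnected: extract the giant connected component first")
    }
    sigma[s] <- 0
    H[s, ] <- sigma
    L[s, ] <- dist
  }
  list(H = H, L = L, diameter = max(L))
}

#' Per-node path-multiplicity degrees
#'
#' The Path Hesitation Degree of node i is the mean geodesic count over all
#' pairs involving i. On any tree (unique geodesics everywhere) every entry
#' is exactly 1.
#'
#' @param result a [path_hesitation] object.
#' @return Named numeric vector of length N.
#' @export
phd_vector <- function(result) {
  stopifnot(inherits(result, "path_hesitation"))
  result$phd
}

#' Network-level path-multiplicity index
#'
#' The Path Hesitation Index is the mean geodesic count over all ordered
#' pairs; it equals the mean of the per-node degrees and is at least 1, with
#' equality exactly when every pair has a unique geodesic (trees, stars,
#' complete graphs).
#'
#' @param result a [path_hesitation] object.
#' @return A single number >= 1.
#' @export
phi_index <- function(result) {
  stopifnot(inherits(result, "path_hesitation"))
  result$phi
}

#' Path-multiplicity index from a pair-count multiset
#'
#' Evaluates the index directly from tallied unordered-pair geodesic counts,
#' for worked examples where the pair multiset is known but the graph is not:
#' \eqn{\Phi = 2 \sum_h h\,c_h / (N(N-1))}. The counts must cover all
#' `N(N-1)/2` unordered pairs.
#'
#' @param h vector of distinct geodesic-count values.
#' @param counts number of unordered pairs attaining each value.
#' @param n_nodes number of nodes N.
#' @return A single number >= 1.
#' @examples
#' # 7-node example: 14 pairs with h=1, 4 with h=2, 2 with h=3, 1 with h=4
#' phi_from_pair_counts(c(1, 2, 3, 4), c(14, 4, 2, 1), 7)  # 1.5238...
#' @export
phi_from_pair_counts <- function(h, counts, n_nodes) {
  stopifnot(length(h) == length(counts), n_nodes >= 2)
  npairs <- n_nodes * (n_nodes - 1) / 2
  if (sum(counts) != npairs) {
    stop(sprintf("pair counts sum to %g but N = %d has %g unordered pairs",
                 sum(counts), n_nodes, npairs))
  }
  2 * sum(h * counts) / (n_nodes * (n_nodes - 1))
}

#' Empirical distribution of pairwise geodesic counts
#'
#' Tallies each unordered node pair once and normalises by `N(N-1)/2`.
#'
#' @param result a [path_hesitation] object.
#' @return A [pm_distribution] with columns `value`, `count`, `prob`.
#' @export
pha_distribution <- function(result) {
  stopifnot(inherits(result, "path_hesitation"))
  h <- result$H[upper.tri(result$H)]
  tab <- table(h)
  pm_distribution(value = as.numeric(names(tab)),
                  count = as.numeric(tab),
                  kind = "pha")
}

#' Empirical discrete distribution container
#'
#' A small data frame of distinct observed values, their pair (or node)
#' counts, and normalised probabilities summing to 1. Produced by
#' [pha_distribution()] and [degree_stats()]; consumed by [fit_power_law()].
#'
#' @param value distinct observed values, ascending.
#' @param count occurrences of each value.
#' @param kind label: `"pha"` or `"degree"`.
#' @return A data frame of class `"pm_distribution"` with attributes `total`
#'   and `kind`.
#' @export
pm_distribution <- function(value, count, kind = "pha") {
  ord <- order(value)
  d <- data.frame(value = value[ord], count = count[ord],
                  prob = count[ord] / sum(count))
  structure(d, class = c("pm_distribution", "data.frame"),
            total = sum(count), kind = kind)
}

#' @export
print.pm_distribution <- function(x, ...) {
  kind <- attr(x, "kind")
  cat(sprintf("Empirical %s distribution: %d support values over %g observations\n",
              if (identical(kind, "degree")) "degree" else "path-multiplicity",
              nrow(x), attr(x, "total")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' @export
print.path_hesitation <- function(x, digits = 4L, ...) {
  cat(sprintf("Path multiplicity of a connected graph (N = %d, method = %s)\n",
              x$n, x$method))
  cat(sprintf("  Path Hesitation Index  Phi = %.*f\n", digits, x$phi))
  cat(sprintf("  diameter = %d, max pairwise count = %g\n",
              x$diameter, max(x$H)))
  invisible(x)
}

#' @export
summary.path_hesitation <- function(object, ...) {
  dist <- pha_distribution(object)
  structure(list(n = object$n, phi = object$phi,
                 diameter = object$diameter,
                 phd_summary = summary(object$phd),
                 distribution = dist,
                 unique_geodesics = all(object$H[upper.tri(object$H)] == 1)),
            class = "summary.path_hesitation")
}

#' @export
print.summary.path_hesitation <- function(x, ...) {
  cat(sprintf("Path multiplicity summary (N = %d)\n", x$n))
  cat(sprintf("  Phi = %.4f  (>= 1; == 1 iff all geodesics unique: %s)\n",
              x$phi, if (x$unique_geodesics) "yes" else "no"))
  cat(sprintf("  diameter = %d\n", x$diameter))
  cat("  per-node path-multiplicity degrees:\n")
  print(x$phd_summary)
  cat("  pairwise count distribution (head):\n")
  print.data.frame(utils::head(as.data.frame(x$distribution), 8L),
                   row.names = FALSE)
  invisible(x)
}

#' @export
plot.path_hesitation <- function(x, ...) {
  d <- pha_distribution(x)
  graphics::plot(d$value, d$prob, log = "xy",
                 xlab = "pairwise geodesic count h",
                 ylab = "P(h)", pch = 19, ...)
  invisible(x)
}
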