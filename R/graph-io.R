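#' Read an undirected simple graph from an edge list
#'
#' Parses a two-column edge list into an undirected [igraph][igraph::igraph]
#' graph. Lines beginning with `#` or `%` are comments; blank lines are
#' skipped. The delimiter (comma vs. whitespace) is auto-detected from the
#' first data line unless given. Node labels may be arbitrary strings; vertex
#' order is first-appearance order. Self-loops and duplicate edges are
#' dropped with a warning giving the counts, since public edge lists commonly
#' contain both and all analyses here assume a simple graph.
#'
#' @param source path to a file, or a connection, containing the edge list.
#' @param delimiter optional single-character field separator; `NULL` (the
#'   default) auto-detects: comma if the first data line contains one,
#'   otherwise any run of whitespace.
#' @return An undirected simple `igraph` graph with a `name` vertex attribute.
#' @seealso [write_edge_list()], [read_adjacency()], [giant_component()]
#' @examples
#' tf <- tempfile()
#' writeLines(c("# toy", "a b", "b c"), tf)
#' g <- read_edge_list(tf)
#' igraph::vcount(g)
#' @export
read_edge_list <- function(source, delimiter = NULL) {
  lines <- readLines(source, warn = FALSE)
  keep <- !grepl("^\\s*([#%]|$)", lines)
  lineno <- which(keep)
  data <- lines[keep]
  if (length(data) == 0L) stop("empty edge list: no data lines found")

  if (is.null(delimiter)) {
    delimiter <- if (grepl(",", data[[1L]])) "," else "[[:space:]]+"
  } else if (delimiter == ",") {
    # literal comma needs no escaping
  } else {
    delimiter <- paste0("[", delimiter, "]+")
  }

  toks <- strsplit(trimws(data), delimiter)
  nt <- lengths(toks)
  if (any(nt != 2L)) {
    bad <- which(nt != 2L)[1L]
    stop(sprintf("malformed edge list line %d: expected 2 tokens, found %d",
                 lineno[bad], nt[bad]))
  }
  u <- vapply(toks, `[[`, character(1), 1L)
  v <- vapply(toks, `[[`, character(1), 2L)

  loops <- u == v
  n_loops <- sum(loops)
  u2 <- u[!loops]; v2 <- v[!loops]
  key <- paste(pmin(u2, v2), pmax(u2, v2))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_loops + n_dup > 0L) {
    warning(sprintf("dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_loops, n_dup))
  }
  nodes <- unique(c(rbind(u, v)))  # first-appearance order, interleaved
  g <- igraph::graph_from_data_frame(
    data.frame(from = u2[!dup], to = v2[!dup], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  g
}

#' Write a graph as a sorted two-column edge list
#'
#' Emits one `u v` line per edge, endpoints ordered within each line by
#' vertex index and lines sorted likewise, so that output is canonical:
#' re-reading reproduces the identical edge set.
#'
#' @param g an undirected `igraph` graph.
#' @param path file path or connection to write to.
#' @param header optional character vector of comment lines (written with a
#'   leading `#`), e.g. a reproducibility header.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, header = NULL) {
  check_simple_undirected(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  swap <- el[, 1L] > el[, 2L]
  el[swap, ] <- el[swap, 2:1]
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  nm <- vertex_labels(g)
  out <- paste(nm[el[, 1L]], nm[el[, 2L]])
  if (!is.null(header)) out <- c(paste("#", header), out)
  writeLines(out, path)
  invisible(path)
}

#' Read a dense 0/1 adjacency matrix
#'
#' Reads a whitespace- or comma-delimited square numeric matrix and converts
#' it to an undirected simple graph. The matrix must be symmetric with zero
#' diagonal and contain only 0/1 entries.
#'
#' @param source path or connection to the matrix text.
#' @return An undirected simple `igraph` graph; vertices are named `1..N`.
#' @export
read_adjacency <- function(source) {
  lines <- readLines(source, warn = FALSE)
  sep <- if (any(grepl(",", lines))) "," else ""
  m <- as.matrix(utils::read.table(text = lines, header = FALSE, sep = sep,
                                   comment.char = "#"))
  m <- unname(m)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("adjacency matrix must be square")
  if (!all(m %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (!isTRUE(all.equal(m, t(m)))) stop("adjacency matrix must be symmetric")
  if (any(diag(m) != 0)) stop("adjacency matrix must have zero diagonal")
  dimnames(m) <- list(as.character(seq_len(nrow(m))),
                      as.character(seq_len(nrow(m))))
  igraph::graph_from_adjacency_matrix(m, mode = "undirected")
}

#' Extract the giant connected component
#'
#' Returns the induced subgraph on the largest connected node set. Ties
#' between equally large components are broken in favour of the component
#' containing the smallest vertex index, so the result is deterministic.
#' The operation is idempotent.
#'
#' @param g an undirected `igraph` graph with at least one vertex.
#' @return A connected `igraph` graph.
#' @export
giant_component <- function(g) {
  check_simple_undirected(g)
  if (igraph::vcount(g) < 1L) stop("graph has no vertices")
  comp <- igraph::components(g)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    first_member <- vapply(big, function(cc) min(which(comp$membership == cc)),
                           numeric(1))
    big <- big[which.min(first_member)]
  }
  igraph::induced_subgraph(g, which(comp$membership == big))
}

#' Degree statistics of a graph
#'
#' Degrees, mean degree, edge density and the empirical degree distribution.
#' Edge density is the mean degree divided by `N - 1`, i.e. the fraction of
#' possible edges present.
#'
#' @param g an undirected simple `igraph` graph with at least 2 vertices.
#' @return A list of class `"degree_stats"` with components `degrees` (named
#'   integer vector), `mean_degree`, `edge_density`, and `distribution` (a
#'   [pm_distribution] over observed degree values).
#' @export
degree_stats <- function(g) {
  check_simple_undirected(g)
  n <- igraph::vcount(g)
  if (n < 2L) stop("degree statistics need at least 2 nodes (density undefined)")
  d <- igraph::degree(g)
  names(d) <- vertex_labels(g)
  tab <- table(d)
  dist <- pm_distribution(value = as.numeric(names(tab)),
                          count = as.numeric(tab),
                          kind = "degree")
  structure(list(degrees = d,
                 mean_degree = mean(d),
                 edge_density = mean(d) / (n - 1),
                 distribution = dist),
            class = "degree_stats")
}

#' @export
print.degree_stats <- function(x, ...) {
  cat(sprintf("Degree statistics: N = %d, <k> = %.4g, edge density = %.4g\n",
              length(x$degrees), x$mean_degree, x$edge_density))
  cat(sprintf("  degree range [%d, %d], %d distinct values\n",
              min(x$degrees), max(x$degrees), nrow(x$distribution)))
  invisible(x)
}

# internal validation shared by every graph-consuming entry point
check_simple_undirected <- function(g) {
  if (!igraph::is_igraph(g)) stop("expected an igraph graph object")
  if (igraph::is_directed(g)) stop("graph must be undirected")
  if (!igraph::is_simple(g)) stop("graph must be simple (no loops or multi-edges)")
  invisible(g)
}

vertex_labels <- function(g) {
  nm <- igraph::vertex_attr(g, "name")
  if (is.null(nm)) as.character(seq_len(igraph::vcount(g))) else as.character(nm)
}

adjacency_dense <- function(g) {
  a <- igraph::as_adjacency_matrix(g, type = "both", sparse = FALSE)
  storage.mode(a) <- "double"
  dimnames(a) <- list(vertex_labels(g), vertex_labels(g))
  a
}
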