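test_that("edge lists parse with comments, both delimiters, and label order", {
  g <- read_edge_list(tmp_edge_file(c("# comment", "% also a comment",
                                      "1 2", "2 3")))
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::V(g)$name, c("1", "2", "3"))

  g2 <- read_edge_list(tmp_edge_file(c("b,a", "a,c")))
  expect_equal(igraph::ecount(g2), 2)
  expect_equal(igraph::V(g2)$name, c("b", "a", "c"))  # first-appearance order
})

test_that("self-loops and duplicate edges are dropped with a warning", {
  expect_warning(
    g <- read_edge_list(tmp_edge_file(c("1 2", "2 1", "1 1"))),
    "1 self-loop.*1 duplicate")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_true(igraph::is_simple(g))
})

test_that("the union of the four worked-example geodesics has 6 nodes and 8 edges", {
  lines <- c("v1 v2", "v2 v3", "v3 v6", "v2 v5",
             "v5 v6", "v1 v4", "v4 v3", "v4 v5")
  g <- read_edge_list(tmp_edge_file(lines))
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 8)
})

test_that("malformed and empty inputs raise informative errors", {
  expect_error(read_edge_list(tmp_edge_file(c("1 2", "3 4 5"))),
               "line 2.*found 3")
  expect_error(read_edge_list(tmp_edge_file(c("# only", "% comments"))),
               "empty")
})

test_that("write/read round-trip preserves the edge set exactly", {
  set.seed(42)
  for (i in 1:5) {
    g <- igraph::sample_gnp(15, 0.25)
    igraph::V(g)$name <- sample(letters[1:15])
    tf <- tempfile()
    write_edge_list(g, tf)
    g2 <- read_edge_list(tf)
    key <- function(gr) {
      el <- igraph::as_edgelist(gr)
      sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
    }
    expect_identical(key(g2), key(g))
  }
})

test_that("adjacency matrices load and validate", {
  a <- matrix(0, 4, 4); a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1
  tf <- tempfile()
  write.table(a, tf, row.names = FALSE, col.names = FALSE)
  g <- read_adjacency(tf)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::vcount(g), 4)

  bad <- a; bad[1, 3] <- 1  # asymmetric
  write.table(bad, tf, row.names = FALSE, col.names = FALSE)
  expect_error(read_adjacency(tf), "symmetric")
})

test_that("loaded graphs always satisfy symmetry and zero diagonal", {
  set.seed(99)
  for (i in 1:5) {
    g <- random_connected_er(20, 0.2)
    a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    expect_identical(a, t(a))
    expect_true(all(diag(a) == 0))
  }
})

test_that("giant component extraction handles the documented cases and is idempotent", {
  g <- read_edge_list(tmp_edge_file(c("1 2", "2 3")))
  expect_equal(igraph::vcount(giant_component(g)), 3)  # connected: identity

  two <- read_edge_list(tmp_edge_file(c("1 2", "2 3", "3 4", "5 6")))
  gc <- giant_component(two)
  expect_equal(igraph::vcount(gc), 4)
  expect_true(igraph::is_connected(gc))
  expect_setequal(igraph::V(gc)$name, c("1", "2", "3", "4"))

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  expect_equal(igraph::vcount(giant_component(edgeless)), 1)

  # idempotence
  gc2 <- giant_component(gc)
  expect_equal(igraph::vcount(gc2), igraph::vcount(gc))
  expect_equal(igraph::ecount(gc2), igraph::ecount(gc))
})

test_that("degree statistics match hand-computed values and normalise", {
  k5 <- make_fixture("complete", n = 5)
  ds <- degree_stats(k5)
  expect_true(all(ds$degrees == 4))
  expect_equal(ds$mean_degree, 4)
  expect_equal(ds$edge_density, 1)

  star10 <- make_fixture("star", n = 10)
  ds2 <- degree_stats(star10)
  expect_equal(ds2$mean_degree, 1.8)
  expect_equal(ds2$edge_density, 0.2)

  ba <- sample_ba(1000, 3, seed = 4)
  dd <- degree_stats(ba)$distribution
  expect_equal(sum(dd$prob), 1)
  expect_gt(max(dd$value), 3 * mean(degree_stats(ba)$degrees))  # heavy tail

  expect_error(degree_stats(igraph::make_empty_graph(1, directed = FALSE)),
               "at least 2")
})
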