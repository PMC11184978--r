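# Frozen expected values for the small topologies come from independent
# enumeration: igraph::all_shortest_paths (a third route, used neither by the
# matrix engine nor the BFS engine) and closed forms for lattices.

test_that("complete graph K4 has single-edge geodesics everywhere", {
  ph <- path_hesitation(make_fixture("complete", n = 4))
  off <- !diag(4)
  expect_true(all(ph$H[off] == 1))
  expect_true(all(ph$L[off] == 1))
  expect_equal(phi_index(ph), 1)
})

test_that("the worked-example union graph reproduces the printed pair values", {
  g <- make_fixture("fig1_union")
  ph <- path_hesitation(g)
  expect_equal(ph$H["v1", "v6"], 4)
  expect_equal(ph$L["v1", "v6"], 3)
  # independent enumeration agrees
  expect_equal(count_geodesics_igraph(g, "v1", "v6"), 4)

  # per-node degree of v1: (1+2+1+2+4)/5 = 2
  expect_equal(phd_vector(ph)[["v1"]], 2)
  # network index over all 15 pairs: (8*1 + 4*2 + 2*3 + 1*4)/15 = 52/30
  expect_equal(phi_index(ph), 52 / 30)

  d <- pha_distribution(ph)
  expect_equal(d$value, c(1, 2, 3, 4))
  expect_equal(d$count, c(8, 4, 2, 1))
  expect_equal(sum(d$prob), 1)
})

test_that("trees and stars have unique geodesics so all indices are 1", {
  for (g in list(make_fixture("tree", n = 15),
                 make_fixture("star", n = 6),
                 make_fixture("tree", n = 5, children = 1))) {  # path P5
    ph <- path_hesitation(g)
    expect_true(all(ph$H[upper.tri(ph$H)] == 1))
    expect_true(all(phd_vector(ph) == 1))
    expect_equal(phi_index(ph), 1)
  }
})

test_that("lattice closed forms hold: grid binomials, hypercube factorials, cycle arcs", {
  # a x b grid: corner-to-corner geodesics are monotone staircases,
  # C((a-1)+(b-1), a-1) of them, of length (a-1)+(b-1)
  for (dims in list(c(4, 4), c(3, 5), c(2, 6))) {
    g <- make_fixture("grid", dims = dims)
    ph <- path_hesitation(g)
    n <- prod(dims)
    expect_equal(ph$H["1", as.character(n)], choose(sum(dims) - 2, dims[1] - 1))
    expect_equal(ph$L["1", as.character(n)], sum(dims) - 2)
  }
  # n-hypercube antipodal pair: n! geodesics of length n
  for (d in 2:4) {
    ph <- path_hesitation(make_fixture("hypercube", n = d))
    expect_equal(max(ph$L), d)
    expect_equal(max(ph$H), factorial(d))
  }
  # even cycle C_{2m}: antipodal pairs have exactly the 2 arcs
  for (m in 2:4) {
    ph <- path_hesitation(make_fixture("ring", n = 2 * m, nei = 1))
    expect_equal(max(ph$L), m)
    expect_true(all(ph$H[ph$L == m] == 2))
  }
})

test_that("matrix-power and BFS engines agree exactly on random graphs", {
  set.seed(2024)
  for (i in 1:60) {
    n <- sample(5:60, 1)
    g <- random_connected_er(n)
    a <- path_hesitation(g, method = "matrix")
    b <- path_hesitation(g, method = "bfs")
    expect_identical(a$H, b$H)
    expect_identical(a$L, b$L)
  }
})

test_that("walk-geodesic identity: h_ij equals the (i,j) entry of A^(l_ij)", {
  set.seed(5)
  for (i in 1:10) {
    g <- random_connected_er(25, 0.15)
    ph <- path_hesitation(g)
    a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    storage.mode(a) <- "double"
    pw <- a
    for (k in seq_len(max(ph$L))) {
      idx <- which(ph$L == k & upper.tri(ph$L))
      expect_true(all(ph$H[idx] == pw[idx]))
      pw <- pw %*% a
    }
  }
})

test_that("lengths agree with igraph BFS distances and phi has its floor", {
  set.seed(31)
  for (i in 1:20) {
    g <- random_connected_er(30, 0.15)
    ph <- path_hesitation(g)
    expect_equal(unname(ph$L), unname(igraph::distances(g)))
    expect_gte(phi_index(ph), 1)
    # phi == 1 iff all geodesics unique
    expect_equal(phi_index(ph) == 1, all(ph$H[upper.tri(ph$H)] == 1))
  }
})

test_that("disconnected or degenerate input is rejected with guidance", {
  two <- igraph::make_full_graph(3) + igraph::make_full_graph(2)
  expect_error(path_hesitation(two), "giant connected component")
  expect_error(path_hesitation(two, method = "bfs"), "giant connected component")
  expect_error(path_hesitation(igraph::make_empty_graph(1, directed = FALSE)),
               "at least 2")
})

test_that("phi_from_pair_counts evaluates the index from a pair multiset", {
  # the printed 7-node example multiset
  expect_equal(round(phi_from_pair_counts(1:4, c(14, 4, 2, 1), 7), 4), 1.5238)
  # must cover all unordered pairs
  expect_error(phi_from_pair_counts(1, 5, 7), "unordered pairs")
})
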