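test_that("degree centrality is the neighbour count", {
  star <- graph_from_edges(star_edges(4))
  sc <- degree_centrality(star)$scores
  expect_equal(unname(sc["1"]), 4)
  expect_equal(unname(sc[c("2", "3", "4", "5")]), rep(1, 4))

  tri <- graph_from_edges(rbind(c(1, 2), c(2, 3), c(3, 1)))
  expect_equal(unname(degree_centrality(tri)$scores), rep(2, 3))

  iso <- graph_from_edges(rbind(c(1, 2)), vertices = 1:3)
  expect_equal(unname(degree_centrality(iso)$scores["3"]), 0)
})

test_that("eigenvector centrality matches closed forms and stays unit-norm", {
  k3 <- graph_from_edges(complete_edges(3))
  expect_equal(unname(eigenvector_centrality(k3)$scores), rep(1 / sqrt(3), 3),
               tolerance = 1e-9)

  # star K_{1,n}: hub / leaf score ratio is sqrt(n)
  star <- graph_from_edges(star_edges(4))
  sc <- eigenvector_centrality(star)$scores
  expect_equal(unname(sc["1"] / sc["2"]), 2, tolerance = 1e-8)
  expect_equal(sum(sc^2), 1, tolerance = 1e-9)

  edgeless <- graph_from_edges(NULL, vertices = 1:4)
  expect_equal(unname(eigenvector_centrality(edgeless)$scores), rep(0, 4))

  # bipartite graphs converge despite the period-2 eigenstructure
  p4 <- graph_from_edges(path_edges(4))
  expect_true(all(eigenvector_centrality(p4)$scores > 0))
})

test_that("closeness uses the within-component mean-distance convention", {
  p3 <- graph_from_edges(path_edges(3))
  sc <- closeness_centrality(p3)$scores
  expect_equal(unname(sc["2"]), 1.5)     # mean distance (0+1+1)/3 = 2/3
  expect_equal(unname(sc["1"]), 1.0)     # mean distance (0+1+2)/3 = 1

  for (n in c(4, 6)) {
    kn <- graph_from_edges(complete_edges(n))
    expect_equal(unname(closeness_centrality(kn)$scores), rep(n / (n - 1), n))
  }

  two_tri <- graph_from_edges(rbind(c(1, 2), c(2, 3), c(3, 1),
                                    c(4, 5), c(5, 6), c(6, 4)))
  expect_equal(unname(closeness_centrality(two_tri)$scores), rep(1.5, 6))

  iso <- graph_from_edges(rbind(c(1, 2)), vertices = 1:3)
  expect_equal(unname(closeness_centrality(iso)$scores["3"]), 0)
})

test_that("betweenness weights geodesics by their multiplicity", {
  p3 <- graph_from_edges(path_edges(3))
  expect_equal(unname(betweenness_centrality(p3)$scores), c(0, 1, 0))

  # C4: each opposite pair has two geodesics, each carrying weight 1/2
  c4 <- graph_from_edges(cycle_edges(4))
  expect_equal(unname(betweenness_centrality(c4)$scores), rep(0.5, 4))

  k5 <- graph_from_edges(complete_edges(5))
  expect_equal(unname(betweenness_centrality(k5)$scores), rep(0, 5))
})

test_that("centrality implementations agree with brute-force oracles on small graphs", {
  check_graph <- function(edges, labels) {
    g <- graph_from_edges(edges, vertices = labels)
    expect_equal(unname(betweenness_centrality(g)$scores),
                 unname(oracle_betweenness(edges, labels)[as.character(vertex_labels(g))]),
                 tolerance = 1e-9)
    expect_equal(unname(closeness_centrality(g)$scores),
                 unname(oracle_closeness(edges, labels)[as.character(vertex_labels(g))]),
                 tolerance = 1e-12)
    if (igraph::ecount(g) > 0) {
      ev <- oracle_eigenvector(edges, labels)
      if (!is.null(ev)) {     # skip (near-)degenerate dominant eigenvalues
        expect_equal(unname(eigenvector_centrality(g)$scores),
                     unname(ev[as.character(vertex_labels(g))]),
                     tolerance = 1e-8)
      }
    }
  }

  # exhaustive over all graphs on 4 labelled vertices
  pairs4 <- t(utils::combn(4, 2))
  for (mask in 0:63) {
    edges <- pairs4[bitwAnd(mask, 2^(0:5)) > 0, , drop = FALSE]
    check_graph(edges, 1:4)
  }
  # random sample of 5- and 6-vertex graphs, plus a few at 7
  for (s in 1:25) check_graph(random_edges(5, 0.5, s), 1:5)
  for (s in 1:25) check_graph(random_edges(6, 0.4, 100 + s), 1:6)
  for (s in 1:8) check_graph(random_edges(7, 0.35, 200 + s), 1:7)
})

test_that("relabelling vertices permutes all four score vectors identically", {
  edges <- random_edges(8, 0.4, 42)
  relab <- c(11L, 3L, 7L, 20L, 1L, 9L, 15L, 6L)   # old label i -> relab[i]
  g1 <- graph_from_edges(edges, vertices = 1:8)
  g2 <- graph_from_edges(matrix(relab[edges], ncol = 2), vertices = relab)
  for (ms in c("degree", "eigenvector", "closeness", "betweenness")) {
    s1 <- centrality(g1, ms)$scores
    s2 <- centrality(g2, ms)$scores
    expect_equal(unname(s2[as.character(relab)]), unname(s1[as.character(1:8)]),
                 tolerance = 1e-7)
  }
})

test_that("adding an edge never lowers a degree score", {
  edges <- random_edges(9, 0.3, 7)
  g <- graph_from_edges(edges, vertices = 1:9)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  free <- which(A == 0 & upper.tri(A), arr.ind = TRUE)[1, ]
  extra <- vertex_labels(g)[free]
  g2 <- graph_from_edges(rbind(edges, extra), vertices = 1:9)
  d1 <- degree_centrality(g)$scores
  d2 <- degree_centrality(g2)$scores
  expect_true(all(d2[names(d1)] >= d1))
})

test_that("degree tracks betweenness and closeness tracks eigenvector on scale-free nets", {
  g <- barabasi_albert(3000, 2, seed = 31)
  expect_gt(centrality_correlation(degree_centrality(g),
                                   betweenness_centrality(g)), 0.7)
  expect_gt(centrality_correlation(closeness_centrality(g),
                                   eigenvector_centrality(g)), 0.3)
})
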