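test_that("R-index is the normalised area under the attack curve", {
  k4 <- graph_from_edges(complete_edges(4))
  tr <- simultaneous_attack(k4, "degree", seed = 1)
  expect_equal(r_index(tr), 0.375)           # (N-1)/(2N), the complete-graph maximum
  expect_equal(v_index(tr), 0.125)

  star <- graph_from_edges(star_edges(4))
  tr2 <- simultaneous_attack(star, "degree", seed = 1)
  expect_equal(r_index(tr2), 4/25)
  expect_equal(v_index(tr2), 0.34)

  p3 <- graph_from_edges(path_edges(3))
  tr3 <- simultaneous_attack(p3, "degree", seed = 1)
  expect_equal(r_index(tr3), 2/9)

  partial <- tr
  partial$s <- partial$s[1:2]
  expect_error(r_index(partial), "partial")
})

test_that("V + R = 1/2 exactly, for single trajectories and averaged lists", {
  gs <- list(random_graph(20, 0.2, 1), growing_random(50, 2, seed = 2))
  for (g in gs) {
    for (ms in c("degree", "betweenness")) {
      tr <- simultaneous_attack(g, ms, seed = 3)
      expect_identical(v_index(tr) + r_index(tr), 0.5)
    }
    rb <- robustness(random_attack(g, seed = 4, reps = 3))
    expect_identical(rb$v_index + rb$r_index, 0.5)
    expect_equal(rb$reps, 3)
  }
})

test_that("complete graphs attain the maximal R under every strategy", {
  for (n in c(5, 9)) {
    kn <- graph_from_edges(complete_edges(n))
    for (ms in c("degree", "eigenvector", "closeness", "betweenness")) {
      expect_equal(r_index(simultaneous_attack(kn, ms, seed = 1)), (n - 1) / (2 * n))
    }
    expect_equal(r_index(random_attack(kn, seed = 2, reps = 1)[[1]]), (n - 1) / (2 * n))
  }
})

test_that("clustering coefficient averages local neighbour-pair fractions", {
  tri <- graph_from_edges(complete_edges(3))
  expect_equal(clustering_coefficient(tri), 1)

  star <- graph_from_edges(star_edges(4))
  expect_equal(clustering_coefficient(star), 0)

  # triangle with one pendant: locals are 1, 1, 1/3, 0
  pend <- graph_from_edges(rbind(c(1, 2), c(2, 3), c(3, 1), c(3, 4)))
  cc <- clustering_coefficient(pend, per_vertex = TRUE)
  expect_equal(unname(cc$local[as.character(1:4)]), c(1, 1, 1/3, 0))
  expect_equal(cc$global, 7/12)

  expect_error(clustering_coefficient(graph_from_edges(NULL)), "empty")
})

test_that("assortativity matches the degree-correlation formula", {
  star <- graph_from_edges(star_edges(6))
  expect_equal(assortativity_coefficient(star), -1)

  c5 <- graph_from_edges(cycle_edges(5))
  expect_true(is.na(assortativity_coefficient(c5)))   # degree-regular

  p4 <- graph_from_edges(path_edges(4))
  expect_equal(assortativity_coefficient(p4), -0.5)

  expect_error(assortativity_coefficient(graph_from_edges(NULL, vertices = 1:3)),
               "edge")
})

test_that("average path length is the mean over reachable pairs", {
  for (n in c(4, 7)) {
    expect_equal(average_path_length(graph_from_edges(complete_edges(n))), 1)
  }
  expect_equal(average_path_length(graph_from_edges(path_edges(3))), 4/3)
  two <- graph_from_edges(rbind(c(1, 2), c(3, 4)))
  expect_equal(average_path_length(two), 1)
  expect_error(average_path_length(graph_from_edges(NULL, vertices = 1:2)),
               "reachable")
})

test_that("centrality correlation is Pearson over the shared vertex set", {
  g <- random_graph(15, 0.3, 5)
  d <- degree_centrality(g)
  expect_equal(centrality_correlation(d, d), 1)

  k4 <- graph_from_edges(complete_edges(4))
  expect_true(is.na(centrality_correlation(degree_centrality(k4),
                                           betweenness_centrality(k4))))

  other <- degree_centrality(random_graph(10, 0.3, 6))
  expect_error(centrality_correlation(d, other), "different")
})

test_that("network_summary reports the seven standard descriptors", {
  star <- graph_from_edges(star_edges(4))
  sm <- network_summary(star)
  expect_equal(sm$n, 5)
  expect_equal(sm$m, 4)
  expect_equal(sm$mean_degree, 1.6)
  expect_equal(sm$components, 1)
  expect_equal(sm$avg_path_length, 1.6)
  expect_equal(sm$clustering, 0)
  expect_equal(sm$assortativity, -1)

  tri <- network_summary(graph_from_edges(complete_edges(3)))
  expect_equal(unlist(tri[c("n", "m", "mean_degree", "components",
                            "avg_path_length", "clustering")], use.names = FALSE),
               c(3, 3, 2, 1, 1, 1))
  expect_true(is.na(tri$assortativity))

  two_tri <- graph_from_edges(rbind(c(1, 2), c(2, 3), c(3, 1),
                                    c(4, 5), c(5, 6), c(6, 4)))
  expect_equal(network_summary(two_tri)$components, 2)
})
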