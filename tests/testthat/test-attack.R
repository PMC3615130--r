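test_that("simultaneous degree attack on a star removes the hub first", {
  star <- graph_from_edges(star_edges(5))
  tr <- simultaneous_attack(star, "degree", seed = 1)
  expect_equal(tr$removal_order[[1]], 1L)
  expect_equal(tr$s, c(1/6, 1/6, 1/6, 1/6, 1/6, 0))
  expect_setequal(tr$removal_order, 1:6)
})

test_that("fully symmetric graphs give the same trajectory whatever the order", {
  k4 <- graph_from_edges(complete_edges(4))
  for (ms in c("degree", "eigenvector", "closeness", "betweenness")) {
    sim <- simultaneous_attack(k4, ms, seed = 2)
    seq_ <- sequential_attack(k4, ms, seed = 3)
    expect_equal(sim$s, c(3/4, 2/4, 1/4, 0))
    expect_equal(seq_$s, sim$s)
  }
  # cycles are vertex-transitive too
  c7 <- graph_from_edges(cycle_edges(7))
  expect_equal(simultaneous_attack(c7, "degree", seed = 4)$s[1],
               sequential_attack(c7, "degree", seed = 5)$s[1])
})

test_that("betweenness targeting picks interior/bridge vertices first", {
  # P4: both interior vertices outrank the leaves; either tie order gives s(1) = 1/2
  p4 <- graph_from_edges(path_edges(4))
  for (s in 1:4) {
    tr <- simultaneous_attack(p4, "betweenness", seed = s)
    expect_true(tr$removal_order[[1]] %in% c(2L, 3L))
    expect_equal(tr$s[[1]], 0.5)
  }

  # two triangles joined by a two-vertex bridge: sequential betweenness takes
  # the bridge out first, leaving two triangles, s(2) = 3/8
  bridge <- graph_from_edges(rbind(c(1, 2), c(2, 3), c(3, 1),
                                   c(3, 4), c(4, 5), c(5, 6),
                                   c(6, 7), c(7, 8), c(8, 6)))
  # the first removal is one of the two bridge vertices; recalculation then
  # demotes the surviving bridge vertex (now a pendant) in favour of the
  # gateway corner of one triangle -- either way two removals leave a
  # triangle as the largest piece
  tr <- sequential_attack(bridge, "betweenness", seed = 6)
  expect_true(tr$removal_order[[1]] %in% c(4L, 5L))
  expect_equal(tr$s[[2]], 3/8)
})

test_that("star attacks are identical under simultaneous and sequential degree targeting", {
  star <- graph_from_edges(star_edges(5))
  sim <- simultaneous_attack(star, "degree", seed = 7)
  seq_ <- sequential_attack(star, "degree", seed = 8)
  expect_equal(seq_$removal_order[[1]], 1L)
  expect_equal(seq_$s, sim$s)
})

test_that("random attack trajectories behave and reproduce", {
  k6 <- graph_from_edges(complete_edges(6))
  trs <- random_attack(k6, seed = 9, reps = 4)
  for (tr in trs) expect_equal(tr$s, (5:0) / 6)

  g <- random_graph(30, 0.15, 3)
  a <- random_attack(g, seed = 10, reps = 3)
  b <- random_attack(g, seed = 10, reps = 3)
  expect_identical(lapply(a, `[[`, "removal_order"),
                   lapply(b, `[[`, "removal_order"))

  # P100 under random removal is far more robust than the K100 floor V = 1/(2N)
  p100 <- graph_from_edges(path_edges(100))
  v_rand <- robustness(random_attack(p100, seed = 11, reps = 10))$v_index
  k100_v <- 0.5 - (100 - 1) / (2 * 100)
  expect_gt(v_rand, k100_v)
})

test_that("trajectories satisfy the percolation invariants on arbitrary graphs", {
  cases <- list(random_graph(40, 0.1, 21), random_graph(25, 0.3, 22),
                growing_random(60, 2, seed = 23))
  for (g in cases) {
    n <- igraph::vcount(g)
    trs <- c(list(simultaneous_attack(g, "degree", seed = 1),
                  simultaneous_attack(g, "betweenness", seed = 2),
                  sequential_attack(g, "closeness", seed = 3),
                  sequential_attack(g, "eigenvector", seed = 4)),
             random_attack(g, seed = 5, reps = 2))
    for (tr in trs) {
      expect_length(tr$s, n)
      expect_true(all(diff(tr$s) <= 1e-12))
      expect_equal(tr$s[[n]], 0)
      expect_setequal(tr$removal_order, vertex_labels(g))
      expect_true(all(tr$s >= 0 & tr$s <= 1))
    }
  }
})

test_that("the union-find trajectory matches from-scratch recomputation", {
  for (s in 1:12) {
    n <- sample(8:35, 1)
    edges <- random_edges(n, 0.2, 300 + s)
    g <- graph_from_edges(edges, vertices = seq_len(n))
    tr <- simultaneous_attack(g, "degree", seed = s)
    expect_equal(tr$s, oracle_s_trajectory(edges, seq_len(n), tr$removal_order),
                 tolerance = 1e-12)
  }
})

test_that("s_curve evaluates the fraction grid against the original size", {
  k4 <- graph_from_edges(complete_edges(4))
  tr <- simultaneous_attack(k4, "degree", seed = 1)
  cv <- s_curve(tr, c(0, 0.5, 1))
  expect_equal(cv$S, c(1, 0.5, 0))

  two <- graph_from_edges(rbind(c(1, 2), c(3, 4)))
  tr2 <- simultaneous_attack(two, "degree", seed = 1)
  expect_equal(s_curve(tr2, 0)$S, 0.5)   # intact largest component fraction

  expect_error(s_curve(tr, c(-0.1)), "fractions")
  expect_error(s_curve(tr, 1.2), "fractions")
})

test_that("attacking an empty graph is refused", {
  empty <- graph_from_edges(NULL)
  expect_error(simultaneous_attack(empty, "degree"), "empty")
  expect_error(sequential_attack(empty, "degree"), "empty")
  expect_error(random_attack(empty), "empty")
})
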