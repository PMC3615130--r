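# Brute-force oracles written directly against edge lists in plain R, kept
# deliberately independent of both the package internals and igraph so they
# can serve as a second route for every quantity they check.

oracle_adjlist <- function(edges, labels) {
  adj <- stats::setNames(vector("list", length(labels)), as.character(labels))
  for (l in labels) adj[[as.character(l)]] <- integer(0)
  if (length(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1L]; b <- edges[i, 2L]
      if (a == b) next
      if (!(b %in% adj[[as.character(a)]])) {
        adj[[as.character(a)]] <- c(adj[[as.character(a)]], b)
        adj[[as.character(b)]] <- c(adj[[as.character(b)]], a)
      }
    }
  }
  adj
}

# Plain queue-based BFS; returns named distances (Inf when unreachable).
oracle_bfs <- function(adj, labels, src) {
  d <- stats::setNames(rep(Inf, length(labels)), as.character(labels))
  d[as.character(src)] <- 0
  queue <- src
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (u in adj[[as.character(v)]]) {
      if (is.infinite(d[[as.character(u)]])) {
        d[as.character(u)] <- d[[as.character(v)]] + 1
        queue <- c(queue, u)
      }
    }
  }
  d
}

oracle_components <- function(adj, labels) {
  seen <- character(0)
  comps <- list()
  for (l in labels) {
    if (as.character(l) %in% seen) next
    d <- oracle_bfs(adj, labels, l)
    comp <- as.integer(names(d)[is.finite(d)])
    seen <- c(seen, as.character(comp))
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Closeness by the direct formula: score = n_c / sum of within-component
# distances (0 for isolated vertices).
oracle_closeness <- function(edges, labels) {
  adj <- oracle_adjlist(edges, labels)
  vapply(labels, function(v) {
    d <- oracle_bfs(adj, labels, v)
    d <- d[is.finite(d)]
    if (length(d) <= 1L) return(0)
    length(d) / sum(d)
  }, numeric(1)) |> stats::setNames(as.character(labels))
}

# Betweenness by exhaustive geodesic enumeration: every shortest path between
# an unordered pair carries weight 1/(number of geodesics); a vertex collects
# the weights of the paths it sits on as an interior vertex.
oracle_betweenness <- function(edges, labels) {
  adj <- oracle_adjlist(edges, labels)
  bt <- stats::setNames(rep(0, length(labels)), as.character(labels))
  if (length(labels) < 3L) return(bt)
  enum_paths <- function(d, t) {
    # all geodesics ending at t, walking predecessors backwards
    if (d[[as.character(t)]] == 0) return(list(t))
    out <- list()
    for (u in adj[[as.character(t)]]) {
      if (is.finite(d[[as.character(u)]]) &&
          d[[as.character(u)]] == d[[as.character(t)]] - 1) {
        for (p in enum_paths(d, u)) out[[length(out) + 1L]] <- c(p, t)
      }
    }
    out
  }
  for (i in seq_along(labels)) {
    s <- labels[[i]]
    d <- oracle_bfs(adj, labels, s)
    for (j in seq_along(labels)) {
      if (i >= j) next
      t <- labels[[j]]
      if (is.infinite(d[[as.character(t)]])) next   # 0/0 pairs contribute 0
      paths <- enum_paths(d, t)
      w <- 1 / length(paths)
      for (p in paths) {
        interior <- p[-c(1L, length(p))]
        for (v in interior) bt[as.character(v)] <- bt[[as.character(v)]] + w
      }
    }
  }
  bt
}

# Dominant eigenvector by dense symmetric eigendecomposition; returns NULL
# when the dominant eigenvalue is (nearly) degenerate, where the eigenvector
# is not unique and no comparison is meaningful.
oracle_eigenvector <- function(edges, labels) {
  n <- length(labels)
  A <- matrix(0, n, n, dimnames = list(labels, labels))
  if (length(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- as.character(edges[i, 1L]); b <- as.character(edges[i, 2L])
      if (a == b) next
      A[a, b] <- 1; A[b, a] <- 1
    }
  }
  e <- eigen(A, symmetric = TRUE)
  if (n > 1L && e$values[1L] - e$values[2L] < 1e-8) return(NULL)
  v <- abs(e$vectors[, 1L])
  stats::setNames(v / sqrt(sum(v^2)), as.character(labels))
}

# Largest-component fraction after each removal, recomputed from scratch.
oracle_s_trajectory <- function(edges, labels, removal_order) {
  n <- length(labels)
  vapply(seq_along(removal_order), function(q) {
    left <- setdiff(labels, removal_order[seq_len(q)])
    if (!length(left)) return(0)
    keep <- length(edges) > 0 &
      edges[, 1L] %in% left & edges[, 2L] %in% left
    sub <- edges[keep, , drop = FALSE]
    comps <- oracle_components(oracle_adjlist(sub, left), left)
    max(lengths(comps)) / n
  }, numeric(1))
}
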