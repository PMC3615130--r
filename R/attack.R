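# Attack engine ---------------------------------------------------------------
#
# All attack modes record s(Q) -- the size of the largest surviving component
# relative to the ORIGINAL vertex count N -- after every single removal,
# Q = 1..N. Fraction grids are derived views (see s_curve()).

new_trajectory <- function(mode, measure, removal_order, s, n_initial, s0, seed) {
  structure(list(mode = mode, measure = measure,
                 removal_order = removal_order, s = s,
                 n_initial = n_initial, s0 = s0, seed = seed),
            class = "attack_trajectory")
}

# s(Q) for Q = 1..N given a full removal order, via reverse union-find.
trajectory_from_order <- function(g, order_idx) {
  n <- igraph::vcount(g)
  edges <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(edges) <- "integer"
  s_trajectory_cpp(n, edges - 1L, order_idx - 1L)
}

attack_measures <- c("degree", "eigenvector", "closeness", "betweenness")

# Scores used for removal ranking. Identical to centrality() except for the
# eigenvector measure on hard spectra: degraded graphs often contain long
# path-like components whose leading eigenvalues are nearly degenerate, so
# plain power iteration may not reach full tolerance in any reasonable number
# of steps. Ranking only needs the argmax, so the engine falls back to an
# implicitly-restarted Lanczos solve (igraph/ARPACK) and, failing that, to
# the best power-iteration iterate.
attack_scores <- function(g, measure) {
  if (measure != "eigenvector") return(centrality(g, measure)$scores)
  pw <- power_iteration(g, tol = 1e-10, max_iter = 3000L)
  x <- if (pw$converged) pw$x else {
    ar <- tryCatch(
      suppressWarnings(igraph::eigen_centrality(g, scale = TRUE)$vector),
      error = function(e) NULL)
    if (!is.null(ar) && all(is.finite(ar))) as.numeric(ar) else pw$x
  }
  score_vector(g, pmax(x, 0))
}

#' Simultaneous targeted attack
#'
#' Ranks every vertex once on the intact network by the chosen centrality
#' measure, then removes vertices one at a time in decreasing rank order
#' (ties broken uniformly at random), recording the relative size of the
#' largest component after every removal.
#'
#' @param g a nonempty graph.
#' @param measure one of `"degree"`, `"eigenvector"`, `"closeness"`,
#'   `"betweenness"`.
#' @param seed RNG seed for tie-breaking.
#' @return an `attack_trajectory`: list with `mode`, `measure`,
#'   `removal_order` (vertex labels, a permutation of the original vertex
#'   set), `s` (s(Q) for Q = 1..N, non-increasing, ending at 0), `n_initial`,
#'   `s0` (largest-component fraction of the intact graph) and `seed`.
#' @examples
#' g <- growing_random(300, 2, seed = 1)
#' traj <- simultaneous_attack(g, "degree", seed = 1)
#' v_index(traj)
#' @export
simultaneous_attack <- function(g, measure = attack_measures, seed = NULL) {
  measure <- match.arg(measure)
  n <- igraph::vcount(g)
  if (n == 0L) stop("cannot attack an empty graph", call. = FALSE)
  labels <- vertex_labels(g)
  scores <- attack_scores(g, measure)
  ord <- with_seed(seed, order(-scores, stats::runif(n)))
  s <- trajectory_from_order(g, ord)
  new_trajectory("simultaneous", measure, labels[ord], s, n,
                 largest_component_fraction(g), seed)
}

#' Sequential targeted attack with recalculation
#'
#' Like [simultaneous_attack()], but the centrality measure is recomputed on
#' the current degraded graph before every removal, and the top-ranked
#' surviving vertex (ties broken uniformly at random) is removed. Isolated
#' vertices created along the way simply score 0 and are removed last.
#'
#' @inheritParams simultaneous_attack
#' @return an `attack_trajectory` (see [simultaneous_attack()]).
#' @export
sequential_attack <- function(g, measure = attack_measures, seed = NULL) {
  measure <- match.arg(measure)
  n0 <- igraph::vcount(g)
  if (n0 == 0L) stop("cannot attack an empty graph", call. = FALSE)
  s <- numeric(n0)
  removal <- integer(n0)
  with_seed(seed, {
    cur <- g
    for (q in seq_len(n0)) {
      sc <- attack_scores(cur, measure)
      ties <- which(sc == max(sc))
      pick <- ties[[sample.int(length(ties), 1L)]]
      lab <- as.integer(names(sc)[pick])
      removal[q] <- lab
      cur <- remove_vertices(cur, lab)
      s[q] <- if (igraph::vcount(cur) == 0L) 0 else
        max(igraph::components(cur)$csize) / n0
    }
  })
  new_trajectory("sequential", measure, removal, s, n0,
                 largest_component_fraction(g), seed)
}

#' Uniformly random attack
#'
#' Removes vertices in a uniformly random order; `reps` independent
#' permutations are generated and each yields a full trajectory. Summary
#' indices over the repetitions are available via [robustness()], which
#' averages when given the whole list.
#'
#' @inheritParams simultaneous_attack
#' @param reps number of independent random permutations (default 10).
#' @return list of `attack_trajectory` objects of length `reps`.
#' @export
random_attack <- function(g, seed = NULL, reps = 10L) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("cannot attack an empty graph", call. = FALSE)
  if (!is_whole(reps) || reps < 1L) stop("`reps` must be >= 1", call. = FALSE)
  labels <- vertex_labels(g)
  s0 <- largest_component_fraction(g)
  with_seed(seed, {
    lapply(seq_len(reps), function(i) {
      ord <- sample.int(n)
      s <- trajectory_from_order(g, ord)
      new_trajectory("random", "none", labels[ord], s, n, s0, seed)
    })
  })
}

#' Largest-component curve S(q) on a fraction grid
#'
#' `S(q)` is the relative largest-component size after removing the fraction
#' `q` of the original vertices: `S(q) = s(ceiling(q * N))`, with `S(0)` equal
#' to the largest-component fraction of the intact graph.
#'
#' @param traj an `attack_trajectory`.
#' @param q_grid numeric vector of removal fractions in `[0, 1]`.
#' @return data frame with columns `q` and `S`.
#' @export
s_curve <- function(traj, q_grid) {
  stopifnot(inherits(traj, "attack_trajectory"))
  if (!is.numeric(q_grid) || any(q_grid < 0 | q_grid > 1)) {
    stop("`q_grid` must contain fractions in [0, 1]", call. = FALSE)
  }
  n <- traj$n_initial
  S <- vapply(q_grid, function(q) {
    Q <- ceiling(q * n)
    if (Q == 0L) traj$s0 else traj$s[[Q]]
  }, numeric(1))
  data.frame(q = q_grid, S = S)
}

#' @export
print.attack_trajectory <- function(x, ...) {
  cat(sprintf("<attack_trajectory> mode = %s, measure = %s, N = %d\n",
              x$mode, x$measure, x$n_initial))
  cat(sprintf("  R = %.4f, V = %.4f\n", r_index(x), v_index(x)))
  invisible(x)
}
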