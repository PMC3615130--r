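# Growth-model internals ------------------------------------------------------
#
# All three growth models share the same skeleton: start from a complete graph
# on m+1 vertices (so every arriving vertex can find m distinct targets) and
# let vertices m+2..n arrive one at a time, each contributing exactly m edges.
# They differ only in how targets are chosen. Degrees used for preferential
# sampling are updated after each arrival completes its m edges.

grow_model <- function(n, m, mode, p_triad = 0) {
  n0 <- m + 1L
  seed_pairs <- utils::combn(n0, 2L)
  n_seed <- ncol(seed_pairs)
  n_total <- n_seed + m * (n - n0)
  from <- integer(n_total)
  to <- integer(n_total)
  from[seq_len(n_seed)] <- seed_pairs[1L, ]
  to[seq_len(n_seed)] <- seed_pairs[2L, ]
  ei <- n_seed

  # degree-proportional sampling uses a stub list: one entry per edge endpoint
  stubs <- integer(2L * n_total)
  stubs[seq_len(2L * n_seed)] <- as.integer(seed_pairs)
  ns <- 2L * n_seed

  adj <- NULL
  if (mode == "hk") {
    adj <- vector("list", n)
    for (v in seq_len(n0)) adj[[v]] <- setdiff(seq_len(n0), v)
  }

  if (n > n0) {
    for (v in (n0 + 1L):n) {
      chosen <- integer(m)
      nc <- 0L
      prev <- NA_integer_
      for (e in seq_len(m)) {
        t <- NA_integer_
        if (mode == "hk" && e > 1L && stats::runif(1L) < p_triad) {
          # triad step: close a triangle with a neighbour of the previous target
          cand <- setdiff(adj[[prev]], c(v, chosen[seq_len(nc)]))
          if (length(cand) > 0L) t <- cand[sample.int(length(cand), 1L)]
        }
        if (is.na(t)) {
          if (mode == "uniform") {
            repeat {
              c0 <- sample.int(v - 1L, 1L)
              if (!(c0 %in% chosen[seq_len(nc)])) { t <- c0; break }
            }
          } else {
            repeat {
              c0 <- stubs[sample.int(ns, 1L)]
              if (!(c0 %in% chosen[seq_len(nc)])) { t <- c0; break }
            }
          }
        }
        nc <- nc + 1L
        chosen[nc] <- t
        prev <- t
        if (mode == "hk") adj[[t]] <- c(adj[[t]], v)
      }
      for (t in chosen) {
        ei <- ei + 1L
        from[ei] <- v
        to[ei] <- t
        stubs[ns + 1L] <- v
        stubs[ns + 2L] <- t
        ns <- ns + 2L
      }
      if (mode == "hk") adj[[v]] <- chosen
    }
  }

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  igraph::add_edges(g, as.integer(rbind(from, to)))
}

check_growth_args <- function(n, m) {
  if (!is_whole(m) || m < 1L) stop("`m` must be a positive integer", call. = FALSE)
  if (!is_whole(n) || n <= m + 1L) {
    stop("`n` must exceed m + 1 (the size of the complete seed graph)", call. = FALSE)
  }
}

#' Barabasi-Albert scale-free network
#'
#' Preferential-attachment growth: starting from a complete graph on `m + 1`
#' vertices, each arriving vertex attaches to `m` distinct existing vertices
#' sampled in proportion to their degrees (repeated degree-proportional draws
#' with rejection of duplicates). The degree distribution is a power law and
#' the mean degree converges to `2m`.
#'
#' @param n number of vertices (must exceed `m + 1`).
#' @param m edges added per arriving vertex.
#' @param seed RNG seed; the same seed always yields the identical edge set.
#' @return a graph with vertex labels `1:n`.
#' @examples
#' g <- barabasi_albert(200, 2, seed = 1)
#' mean(igraph::degree(g))
#' @export
barabasi_albert <- function(n, m, seed = NULL) {
  check_growth_args(n, m)
  with_seed(seed, grow_model(as.integer(n), as.integer(m), "pa"))
}

#' Growing random network with exponential degree distribution
#'
#' Identical growth to [barabasi_albert()] except that each arriving vertex
#' attaches to `m` distinct existing vertices chosen uniformly at random,
#' which produces an exponential (rather than power-law) degree distribution.
#'
#' @inheritParams barabasi_albert
#' @return a graph with vertex labels `1:n`.
#' @export
growing_random <- function(n, m, seed = NULL) {
  check_growth_args(n, m)
  with_seed(seed, grow_model(as.integer(n), as.integer(m), "uniform"))
}

#' Holme-Kim scale-free network with tunable clustering
#'
#' Barabasi-Albert growth with triad formation: after the first (always
#' preferential) edge of an arrival, each subsequent edge goes, with
#' probability `p_triad`, to a uniformly chosen neighbour of the previous
#' target (closing a triangle), falling back to preferential attachment when
#' no eligible neighbour exists. Each arrival still contributes exactly `m`
#' edges, so the edge count and mean degree are identical across `p_triad`
#' values; only the clustering coefficient changes.
#'
#' @inheritParams barabasi_albert
#' @param p_triad probability in `[0, 1]` of a triad-formation step.
#' @return a graph with vertex labels `1:n`.
#' @export
holme_kim <- function(n, m, p_triad, seed = NULL) {
  check_growth_args(n, m)
  if (!is.numeric(p_triad) || length(p_triad) != 1L || is.na(p_triad) ||
      p_triad < 0 || p_triad > 1) {
    stop("`p_triad` must be a probability in [0, 1]", call. = FALSE)
  }
  with_seed(seed, grow_model(as.integer(n), as.integer(m), "hk", p_triad))
}

#' Calibrate the Holme-Kim triad probability to a target clustering
#'
#' Bisection on `p_triad` against the mean global clustering coefficient of
#' `pilots` pilot graphs per probe, until the pilot mean is within `tol` of
#' `target_C`. A final graph is then generated at the calibrated probability
#' (re-drawing up to five times so the returned graph itself satisfies the
#' tolerance).
#'
#' @inheritParams holme_kim
#' @param target_C desired global clustering coefficient in `[0, 1]`.
#' @param tol acceptable deviation `|C - target_C|` (default 0.02).
#' @param pilots pilot graphs averaged per bisection probe (default 3).
#' @return list with elements `p_triad` (calibrated probability), `graph`
#'   (one realisation at that probability) and `clustering` (its global C).
#' @export
calibrate_holme_kim <- function(n, m, target_C, tol = 0.02, seed = NULL,
                                pilots = 3L) {
  check_growth_args(n, m)
  if (!is.numeric(target_C) || target_C < 0 || target_C > 1) {
    stop("`target_C` must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 500L)
    used <- 0L
    next_seed <- function() {
      used <<- used + 1L
      sub_seeds[used]
    }
    probe <- function(p) {
      mean(vapply(seq_len(pilots), function(i) {
        clustering_coefficient(holme_kim(n, m, p, seed = next_seed()))
      }, numeric(1)))
    }
    c_max <- probe(1)
    if (target_C > c_max + tol) {
      stop(sprintf(paste0("unreachable target clustering %.3f: the maximum ",
                          "achievable at p_triad = 1 is about %.3f"),
                   target_C, c_max), call. = FALSE)
    }
    c_min <- probe(0)
    if (target_C <= c_min + tol) {
      p_star <- 0
    } else if (target_C >= c_max - tol) {
      p_star <- 1
    } else {
      lo <- 0; hi <- 1
      p_star <- NA_real_
      for (it in seq_len(25L)) {
        mid <- (lo + hi) / 2
        c_mid <- probe(mid)
        if (abs(c_mid - target_C) <= tol) { p_star <- mid; break }
        if (c_mid < target_C) lo <- mid else hi <- mid
      }
      if (is.na(p_star)) p_star <- (lo + hi) / 2
    }
    for (attempt in seq_len(5L)) {
      g <- holme_kim(n, m, p_star, seed = next_seed())
      cc <- clustering_coefficient(g)
      if (abs(cc - target_C) <= tol) {
        return(list(p_triad = p_star, graph = g, clustering = cc))
      }
    }
    stop(sprintf("calibration failed: could not realise clustering %.3f +/- %.3f",
                 target_C, tol), call. = FALSE)
  })
}

#' Degree-preserving rewiring to a target assortativity
#'
#' Implements two-edge rewiring in the style of Xulvi-Brunet and Sokolov: draw
#' two random edges with four distinct endpoints, sort the endpoints by
#' degree, and reconnect them either assortatively (highest with second
#' highest) or disassortatively (highest with lowest), rejecting any move that
#' would create a self-loop or duplicate edge. Directed moves first drive the
#' assortativity coefficient slightly past the target (by `overshoot`); the
#' edge set then relaxes back through the target under purely random
#' degree-preserving pairings, so the configuration delivered at `target_r`
#' is a mixed one rather than the first (maximally sorted) configuration the
#' directed moves encounter. A graph that cannot reach
#' `target_r + overshoot` admits no such mixed configuration and raises an
#' error carrying the best-achieved r. The degree of every vertex -- and
#' hence the whole degree sequence -- is exactly preserved.
#'
#' @param g a graph with at least two edges and non-constant degrees.
#' @param target_r desired degree assortativity in `(-1, 1)`.
#' @param tol stop when `|r - target_r| <= tol` (default 0.005).
#' @param max_steps total proposal budget (default `2000 * ecount(g)`);
#'   exhausting it before the target is reached raises an error carrying the
#'   best-achieved r.
#' @param seed RNG seed.
#' @param overshoot how far past the target the directed drive goes before
#'   the random mix-back (default 0.02, in r units).
#' @param passes number of drive/mix-back passes (default 1).
#' @return the rewired graph (same vertices and labels, same degree sequence).
#' @export
rewire_to_assortativity <- function(g, target_r, tol = 0.005, max_steps = NULL,
                                    seed = NULL, overshoot = 0.02,
                                    passes = 1L) {
  if (!is.numeric(target_r) || target_r <= -1 || target_r >= 1) {
    stop("`target_r` must lie in (-1, 1)", call. = FALSE)
  }
  m_edges <- igraph::ecount(g)
  if (m_edges < 2L) stop("rewiring needs at least two edges", call. = FALSE)
  r0 <- assortativity_coefficient(g)
  if (is.na(r0)) {
    stop("assortativity is undefined for this graph (all degrees equal)",
         call. = FALSE)
  }
  if (abs(r0 - target_r) <= tol) return(g)
  if (is.null(max_steps)) max_steps <- 2000 * m_edges
  edges <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  res <- with_seed(seed, rewire_assort_cpp(
    edges - 1L, igraph::vcount(g), as.numeric(deg), target_r, tol, overshoot,
    as.integer(passes), as.integer(max(1L, m_edges %/% 2L)),
    as.numeric(max_steps)))
  if (!res$converged) {
    stop(sprintf(paste0("could not reach target assortativity %.4f (plus the ",
                        "%.3f mixing margin) within the proposal budget; ",
                        "best achieved r = %.4f"),
                 target_r, overshoot, res$r), call. = FALSE)
  }
  g2 <- igraph::make_empty_graph(n = igraph::vcount(g), directed = FALSE)
  igraph::V(g2)$name <- igraph::V(g)$name
  igraph::add_edges(g2, as.integer(t(res$edges + 1L)))
}
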