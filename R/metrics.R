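# Robustness indices and descriptive network statistics.

check_full_trajectory <- function(traj) {
  if (!inherits(traj, "attack_trajectory")) {
    stop("expected an attack_trajectory", call. = FALSE)
  }
  if (length(traj$s) != traj$n_initial) {
    stop("trajectory is partial: need s(Q) for every Q = 1..N", call. = FALSE)
  }
}

#' Schneider R-index of an attack trajectory
#'
#' `R = (1/N) * sum_{Q=1}^{N} s(Q)`: the size-normalised area under the
#' largest-component curve. The normalisation by N makes networks of
#' different sizes comparable; R is maximised, at `(N - 1) / (2N)`, by the
#' complete graph and approaches its minimum on the star graph under
#' hub-first removal.
#'
#' @param traj a full `attack_trajectory` (one s value per removal).
#' @return the R-index, a number in `[0, (N - 1) / (2N)]`.
#' @export
r_index <- function(traj) {
  check_full_trajectory(traj)
  mean(traj$s)
}

#' Vulnerability V-index of an attack trajectory
#'
#' The complementary quantity to the R-index: `V = 1/2 - R`, where 1/2 is the
#' large-N supremum of R (attained in the limit by complete graphs). High V
#' means the attack fragments the network quickly.
#'
#' @inheritParams r_index
#' @return the V-index.
#' @export
v_index <- function(traj) {
  0.5 - r_index(traj)
}

#' Robustness summary of one or several trajectories
#'
#' For a single trajectory returns its R- and V-index with the attack
#' metadata. For a list of trajectories (e.g. the repetitions of
#' [random_attack()]) returns the indices averaged over the list.
#'
#' @param x an `attack_trajectory` or a list of them.
#' @return a `robustness_result`: list with `r_index`, `v_index`, `measure`,
#'   `mode`, `seed` and `reps`.
#' @export
robustness <- function(x) {
  if (inherits(x, "attack_trajectory")) x <- list(x)
  if (!length(x) || !all(vapply(x, inherits, logical(1), "attack_trajectory"))) {
    stop("expected an attack_trajectory or a nonempty list of them", call. = FALSE)
  }
  r <- mean(vapply(x, r_index, numeric(1)))
  structure(list(r_index = r, v_index = 0.5 - r,
                 measure = x[[1L]]$measure, mode = x[[1L]]$mode,
                 seed = x[[1L]]$seed, reps = length(x)),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("<robustness_result> mode = %s, measure = %s (reps = %d)\n",
              x$mode, x$measure, x$reps))
  cat(sprintf("  R = %.4f, V = %.4f\n", x$r_index, x$v_index))
  invisible(x)
}

#' Global (and local) clustering coefficient
#'
#' The local clustering coefficient of vertex i is the fraction of its
#' neighbour pairs that are themselves adjacent; vertices with degree below 2
#' have no neighbour pairs and score 0. The global coefficient is the mean of
#' the local coefficients over all vertices.
#'
#' @param g a nonempty graph.
#' @param per_vertex if `TRUE`, also return the per-vertex map.
#' @return the global coefficient, or (with `per_vertex = TRUE`) a list with
#'   `global` and `local` (named by vertex label).
#' @export
clustering_coefficient <- function(g, per_vertex = FALSE) {
  if (igraph::vcount(g) == 0L) stop("empty graph", call. = FALSE)
  local <- igraph::transitivity(g, type = "local", isolates = "zero")
  local[is.na(local)] <- 0
  if (!per_vertex) return(mean(local))
  names(local) <- as.character(vertex_labels(g))
  list(global = mean(local), local = local)
}

#' Degree assortativity coefficient
#'
#' Newman's r: the Pearson correlation of the degrees at the two ends of an
#' edge (each edge counted in both orientations). Positive r means hubs link
#' to hubs (assortative); negative r means hubs link to leaves
#' (disassortative).
#'
#' @param g a graph with at least one edge.
#' @return r in `[-1, 1]`, or `NA` when all degrees are equal (the
#'   denominator vanishes, e.g. on cycles and complete graphs).
#' @export
assortativity_coefficient <- function(g) {
  if (igraph::ecount(g) < 1L) stop("assortativity needs at least one edge",
                                   call. = FALSE)
  r <- suppressWarnings(igraph::assortativity_degree(g, directed = FALSE))
  if (is.nan(r)) NA_real_ else r
}

#' Average shortest-path length
#'
#' Mean geodesic distance over all unordered reachable pairs, i.e. computed
#' within components, so the quantity is defined for fragmented graphs too.
#'
#' @param g a graph with at least one edge.
#' @return the mean path length (>= 1).
#' @export
average_path_length <- function(g) {
  if (igraph::ecount(g) < 1L) {
    stop("average path length needs at least one reachable pair", call. = FALSE)
  }
  igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
}

#' Pearson correlation between two centrality score vectors
#'
#' @param a,b `centrality_scores` computed on the same graph snapshot.
#' @return the Pearson correlation over common vertices, or `NA` when either
#'   vector has zero variance.
#' @export
centrality_correlation <- function(a, b) {
  stopifnot(inherits(a, "centrality_scores"), inherits(b, "centrality_scores"))
  common <- intersect(names(a$scores), names(b$scores))
  if (length(common) != length(a$scores) || length(common) != length(b$scores)) {
    stop("score vectors cover different vertex sets", call. = FALSE)
  }
  x <- a$scores[common]
  y <- b$scores[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Descriptive summary of a network
#'
#' The seven standard descriptors: vertex count N, edge count M, mean degree
#' k, number of connected components, average path length (within
#' components), global clustering coefficient, and degree assortativity
#' (`NA` when undefined).
#'
#' @param g a nonempty graph.
#' @return a one-row data frame with columns `n`, `m`, `mean_degree`,
#'   `components`, `avg_path_length`, `clustering`, `assortativity`.
#' @export
network_summary <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty graph", call. = FALSE)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  data.frame(
    n = n,
    m = m,
    mean_degree = 2 * m / n,
    components = igraph::components(g)$no,
    avg_path_length = if (m > 0L) average_path_length(g) else NA_real_,
    clustering = clustering_coefficient(g),
    assortativity = if (m > 0L) assortativity_coefficient(g) else NA_real_
  )
}
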