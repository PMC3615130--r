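#' @rdname centrality
#' @export
degree_centrality <- function(g) {
  new_centrality_scores("degree", score_vector(g, igraph::degree(g)))
}

#' @rdname centrality
#' @param tol convergence tolerance of the power iteration: iterates must
#'   differ by less than `tol` in the max norm (default 1e-10).
#' @param max_iter maximum power-iteration steps (default 10000).
#' @export
eigenvector_centrality <- function(g, tol = 1e-10, max_iter = 10000L) {
  n <- igraph::vcount(g)
  if (n < 1L) stop("eigenvector centrality needs at least one vertex", call. = FALSE)
  if (igraph::ecount(g) == 0L) {
    return(new_centrality_scores("eigenvector", score_vector(g, rep(0, n))))
  }
  pw <- power_iteration(g, tol, max_iter)
  if (!pw$converged) {
    stop(sprintf("power iteration did not converge (residual %.3e after %d iterations)",
                 pw$residual, max_iter), call. = FALSE)
  }
  new_centrality_scores("eigenvector", score_vector(g, pw$x))
}

# Power iteration on A + I for the dominant eigenvector: the shift removes
# the period-2 oscillation that plain iteration exhibits on bipartite graphs
# without changing the eigenvectors. Deterministic all-ones start vector;
# iterates kept at unit Euclidean norm; convergence judged in the max norm.
power_iteration <- function(g, tol, max_iter) {
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  x <- rep(1 / sqrt(n), n)
  converged <- FALSE
  residual <- NA_real_
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) break
    y <- y / nrm
    residual <- max(abs(y - x))
    x <- y
    if (residual < tol) { converged <- TRUE; break }
  }
  list(x = x, residual = residual, converged = converged)
}

#' @rdname centrality
#' @export
closeness_centrality <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) return(new_centrality_scores("closeness", score_vector(g, numeric(0))))
  comp <- igraph::components(g)
  csize <- comp$csize[comp$membership]
  # igraph's closeness is 1 / (sum of distances to reachable vertices); the
  # within-component mean-distance convention used here rescales by the
  # component size n_c (the self term contributes zero to the sum), giving
  # score = n_c / sum(d). Isolated vertices score 0.
  cl <- suppressWarnings(igraph::closeness(g, mode = "all", normalized = FALSE))
  sc <- csize * cl
  sc[!is.finite(sc)] <- 0
  new_centrality_scores("closeness", score_vector(g, sc))
}

#' @rdname centrality
#' @export
betweenness_centrality <- function(g) {
  sc <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  new_centrality_scores("betweenness", score_vector(g, sc))
}

#' Vertex centrality measures
#'
#' The four importance measures used to rank vertices for targeted attack:
#'
#' * **degree**: the number of neighbours of each vertex.
#' * **eigenvector**: entries of the dominant eigenvector of the adjacency
#'   matrix (all non-negative by Perron-Frobenius, returned with unit
#'   Euclidean norm), computed by power iteration on `A + I`. On a
#'   disconnected graph the mass concentrates on the component with the
#'   largest eigenvalue; other components score near 0.
#' * **closeness**: the reciprocal of the mean geodesic (shortest-path)
#'   distance from the vertex to the vertices of its own component, with the
#'   component size as the divisor (the self distance contributes zero).
#' * **betweenness**: for every unordered vertex pair `{s, t}`, each geodesic
#'   between them carries weight `1 / g_st` (`g_st` = number of geodesics);
#'   a vertex's score is the total weight of the geodesics passing through
#'   it, endpoints excluded. Pairs in different components contribute 0.
#'
#' @param g a graph.
#' @param measure one of `"degree"`, `"eigenvector"`, `"closeness"`,
#'   `"betweenness"`.
#' @return a `centrality_scores` object: list with `measure` and `scores`
#'   (a numeric vector named by vertex label, all entries non-negative).
#' @examples
#' g <- graph_from_edges(rbind(c(1, 2), c(2, 3)))  # path a-b-c
#' centrality(g, "betweenness")$scores              # centre scores 1
#' @export
centrality <- function(g, measure = c("degree", "eigenvector", "closeness",
                                      "betweenness")) {
  measure <- match.arg(measure)
  switch(measure,
         degree = degree_centrality(g),
         eigenvector = eigenvector_centrality(g),
         closeness = closeness_centrality(g),
         betweenness = betweenness_centrality(g))
}

score_vector <- function(g, values) {
  v <- as.numeric(values)
  names(v) <- as.character(vertex_labels(g))
  v
}

new_centrality_scores <- function(measure, scores) {
  structure(list(measure = measure, scores = scores),
            class = "centrality_scores")
}

#' @export
print.centrality_scores <- function(x, ...) {
  cat(sprintf("<centrality_scores> measure = %s, %d vertices\n",
              x$measure, length(x$scores)))
  if (length(x$scores) > 0L) {
    top <- sort(x$scores, decreasing = TRUE)
    top <- utils::head(top, 5L)
    cat("  top:", paste(sprintf("%s=%.4g", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}
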