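#' Build a simple undirected graph from integer-labelled edge pairs
#'
#' Self-pairs are dropped and duplicate pairs collapsed, so the result is
#' always a simple undirected graph. Vertex labels are stable integers: they
#' survive vertex deletion unchanged, and every other function in the package
#' refers to vertices by label, never by position.
#'
#' @param edges a two-column matrix/data frame of integer labels, a list of
#'   length-2 integer vectors, or `NULL` for an edgeless graph.
#' @param vertices optional integer vector of labels to include even when
#'   isolated (i.e. not mentioned in `edges`).
#' @return an [igraph::igraph] object whose vertex names are the labels.
#' @examples
#' g <- graph_from_edges(rbind(c(0, 1), c(1, 2), c(2, 0)))
#' vertex_labels(g)
#' @export
graph_from_edges <- function(edges = NULL, vertices = NULL) {
  if (is.null(edges) || (is.list(edges) && length(edges) == 0L) ||
      (is.matrix(edges) && nrow(edges) == 0L)) {
    ends <- matrix(integer(0), ncol = 2L)
  } else {
    if (is.data.frame(edges)) edges <- as.matrix(edges)
    if (is.list(edges) && !is.matrix(edges)) {
      if (!all(lengths(edges) == 2L)) {
        stop("each element of `edges` must be a pair of vertex labels", call. = FALSE)
      }
      edges <- do.call(rbind, lapply(edges, as.vector))
    }
    if (!is.matrix(edges) || ncol(edges) != 2L) {
      stop("`edges` must have two columns (one edge per row)", call. = FALSE)
    }
    if (!is_whole(edges)) {
      stop("vertex labels must be integers", call. = FALSE)
    }
    ends <- matrix(as.integer(edges), ncol = 2L)
  }
  if (!is.null(vertices)) {
    if (!is_whole(vertices)) stop("vertex labels must be integers", call. = FALSE)
    vertices <- as.integer(vertices)
  }
  ends <- ends[ends[, 1L] != ends[, 2L], , drop = FALSE]          # self-pairs
  if (nrow(ends) > 0L) {
    key <- paste(pmin(ends[, 1L], ends[, 2L]), pmax(ends[, 1L], ends[, 2L]))
    ends <- ends[!duplicated(key), , drop = FALSE]                # multi-edges
  }
  labels <- sort(unique(c(as.integer(ends), vertices)))
  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  igraph::V(g)$name <- as.character(labels)
  if (nrow(ends) > 0L) {
    idx <- match(as.integer(t(ends)), labels)
    g <- igraph::add_edges(g, idx)
  }
  g
}

#' Vertex labels of a graph
#'
#' @param g a graph created by this package.
#' @return integer vector of stable vertex labels, in internal vertex order.
#' @export
vertex_labels <- function(g) {
  if (igraph::vcount(g) == 0L) return(integer(0))
  nm <- igraph::V(g)$name
  if (is.null(nm)) stop("graph has no vertex labels; build it with graph_from_edges()",
                        call. = FALSE)
  as.integer(nm)
}

#' Remove vertices (and their incident edges) from a graph
#'
#' Returns a new graph; the input is never modified. Remaining vertices keep
#' their labels, which is what makes sequential attack bookkeeping unambiguous.
#'
#' @param g a graph.
#' @param labels integer labels of the vertices to delete.
#' @return the degraded graph.
#' @export
remove_vertices <- function(g, labels) {
  if (!is_whole(labels)) stop("vertex labels must be integers", call. = FALSE)
  labels <- as.integer(labels)
  present <- vertex_labels(g)
  missing <- setdiff(labels, present)
  if (length(missing) > 0L) {
    stop("unknown vertex label(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  igraph::delete_vertices(g, as.character(labels))
}

#' Connected components of a graph
#'
#' @param g a graph.
#' @return list of integer label vectors (each sorted increasing), ordered by
#'   decreasing size with ties broken by the smallest contained label, so the
#'   largest component is always first.
#' @export
graph_components <- function(g) {
  if (igraph::vcount(g) == 0L) return(list())
  comp <- igraph::components(g)
  labs <- vertex_labels(g)
  parts <- split(labs, comp$membership)
  parts <- lapply(parts, sort)
  sizes <- lengths(parts)
  mins <- vapply(parts, min, numeric(1))
  parts <- parts[order(-sizes, mins)]
  names(parts) <- NULL
  parts
}

#' Breadth-first shortest-path distances from one vertex
#'
#' @param g a graph.
#' @param source label of the source vertex.
#' @return named numeric vector of hop counts to every vertex in the source's
#'   component (including `source` itself at distance 0); vertices in other
#'   components are absent.
#' @export
bfs_distances <- function(g, source) {
  if (!is_whole(source) || length(source) != 1L) {
    stop("`source` must be a single integer label", call. = FALSE)
  }
  if (!(as.integer(source) %in% vertex_labels(g))) {
    stop("unknown vertex label: ", source, call. = FALSE)
  }
  d <- igraph::distances(g, v = as.character(as.integer(source)),
                         algorithm = "unweighted")[1L, ]
  d <- d[is.finite(d)]
  names(d) <- as.character(as.integer(names(d)))
  d
}

# Fraction of vertices in the largest component (1 for the empty-graph limit
# never arises here; callers guard empty graphs).
largest_component_fraction <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) return(0)
  if (igraph::ecount(g) == 0L) return(1 / n)
  max(igraph::components(g)$csize) / n
}
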