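# File formats: plain edge list is the canonical interchange format
# (whitespace-delimited integer pairs, '#' comments); GML is supported
# read-only for common public network files.

#' Read a graph from an edge-list or GML file
#'
#' Directed input is symmetrised and self-loops/duplicate edges are dropped
#' (with a message reporting how many), so the result is always a simple
#' undirected graph.
#'
#' @param path file to read.
#' @param format `"edgelist"` (whitespace-delimited integer pairs, `#`
#'   comments allowed) or `"gml"`.
#' @return a graph.
#' @export
read_graph_file <- function(path, format = c("edgelist", "gml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edgelist") {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    keep <- which(trimws(lines) != "")
    pairs <- matrix(integer(0), ncol = 2L)
    if (length(keep) > 0L) {
      toks <- strsplit(trimws(lines[keep]), "[[:space:]]+")
      bad <- which(lengths(toks) != 2L)
      if (length(bad) > 0L) {
        stop(sprintf("cannot parse line %d of %s: expected two vertex labels",
                     keep[bad[1L]], path), call. = FALSE)
      }
      vals <- suppressWarnings(as.numeric(unlist(toks)))
      if (anyNA(vals) || any(vals != round(vals))) {
        bad <- keep[which(apply(matrix(is.na(vals) | vals != round(vals),
                                       ncol = 2L, byrow = TRUE), 1L, any))[1L]]
        stop(sprintf("cannot parse line %d of %s: labels must be integers",
                     bad, path), call. = FALSE)
      }
      pairs <- matrix(as.integer(vals), ncol = 2L, byrow = TRUE)
    }
    n_raw <- nrow(pairs)
    g <- graph_from_edges(pairs)
    dropped <- n_raw - igraph::ecount(g)
    if (dropped > 0L) {
      message(sprintf("dropped %d self-loop/duplicate edge(s) while reading %s",
                      dropped, path))
    }
    return(g)
  }
  raw <- igraph::read_graph(path, format = "gml")
  ids <- igraph::vertex_attr(raw, "id")
  if (is.null(ids)) ids <- seq_len(igraph::vcount(raw)) - 1L
  el <- igraph::as_edgelist(raw, names = FALSE)
  pairs <- matrix(as.integer(ids[el]), ncol = 2L)
  n_raw <- nrow(pairs)
  g <- graph_from_edges(pairs, vertices = as.integer(ids))
  dropped <- n_raw - igraph::ecount(g)
  if (dropped > 0L) {
    message(sprintf("dropped %d self-loop/duplicate/reciprocal edge(s) while reading %s",
                    dropped, path))
  }
  g
}

#' Write a graph as a plain edge list
#'
#' One `from to` pair per line, deterministic order; isolated vertices are
#' recorded in a `# vertices:` header comment so the file round-trips.
#'
#' @param g a graph.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(g, path) {
  labs <- vertex_labels(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  a <- pmin(labs[el[, 1L]], labs[el[, 2L]])
  b <- pmax(labs[el[, 1L]], labs[el[, 2L]])
  ord <- order(a, b)
  iso <- setdiff(labs, unique(c(a, b)))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(iso) > 0L) {
    writeLines(paste("# vertices:", paste(iso, collapse = " ")), con)
  }
  if (nrow(el) > 0L) writeLines(paste(a[ord], b[ord]), con)
  invisible(path)
}

# Internal: also pick up isolated vertices recorded by write_graph_file().
read_edgelist_with_isolates <- function(path) {
  header <- grep("^# vertices:", readLines(path, warn = FALSE), value = TRUE)
  g <- read_graph_file(path, "edgelist")
  if (length(header) > 0L) {
    iso <- as.integer(strsplit(trimws(sub("^# vertices:", "", header[1L])),
                               "[[:space:]]+")[[1L]])
    g <- graph_from_edges(cbind(vertex_labels(g)[igraph::as_edgelist(g, names = FALSE)[, 1L]],
                                vertex_labels(g)[igraph::as_edgelist(g, names = FALSE)[, 2L]]),
                          vertices = c(vertex_labels(g), iso))
  }
  g
}

flatten_trajectories <- function(trajectories) {
  if (inherits(trajectories, "attack_trajectory")) trajectories <- list(trajectories)
  out <- list()
  for (tr in trajectories) {
    if (inherits(tr, "attack_trajectory")) {
      out[[length(out) + 1L]] <- tr
    } else if (is.list(tr)) {
      for (t2 in tr) {
        stopifnot(inherits(t2, "attack_trajectory"))
        out[[length(out) + 1L]] <- t2
      }
    } else {
      stop("`trajectories` must contain attack_trajectory objects", call. = FALSE)
    }
  }
  out
}

#' Write attack results to CSV files
#'
#' Writes up to four files into `outdir`:
#' * `s_curve.csv`: one row per removal per trajectory (`mode`, `measure`,
#'   `rep`, `Q`, `q`, `s`);
#' * `v_index.csv`: V-indices as a measure-by-mode table;
#' * `summary.csv`: descriptive network statistics;
#' * `s_curve.png` (optional, needs ggplot2): the strategies overlaid.
#'
#' Floats are written at 6 decimals and row order is deterministic, so a
#' rerun with the same configuration and seed produces byte-identical files.
#'
#' @param trajectories list of `attack_trajectory` objects (nested lists, as
#'   returned by [random_attack()], are flattened).
#' @param results list of `robustness_result` objects for the V-index table.
#' @param summaries list of [network_summary()] rows (or `NULL`).
#' @param outdir output directory (created if needed).
#' @param plot also write `s_curve.png` (requires ggplot2).
#' @return character vector of the files written, invisibly.
#' @export
write_results <- function(trajectories, results = list(), summaries = NULL,
                          outdir = ".", plot = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  fmt <- function(x) sprintf("%.6f", x)

  trajs <- flatten_trajectories(trajectories)
  rows <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    data.frame(mode = tr$mode, measure = tr$measure, rep = i,
               Q = seq_len(tr$n_initial),
               q = fmt(seq_len(tr$n_initial) / tr$n_initial),
               s = fmt(tr$s))
  })
  sc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mode = character(0), measure = character(0), rep = integer(0),
               Q = integer(0), q = character(0), s = character(0))
  sc <- sc[order(sc$mode, sc$measure, sc$rep, sc$Q), ]
  f <- file.path(outdir, "s_curve.csv")
  utils::write.csv(sc, f, row.names = FALSE, quote = FALSE)
  written <- c(written, f)

  if (inherits(results, "robustness_result")) results <- list(results)
  vt <- if (length(results)) {
    long <- do.call(rbind, lapply(results, function(r) {
      data.frame(measure = r$measure, mode = r$mode, v_index = r$v_index)
    }))
    measures <- unique(long$measure)
    modes <- unique(long$mode)
    wide <- data.frame(measure = measures)
    for (md in modes) {
      wide[[md]] <- vapply(measures, function(ms) {
        hit <- long$v_index[long$measure == ms & long$mode == md]
        if (length(hit)) fmt(hit[1L]) else NA_character_
      }, character(1))
    }
    wide
  } else data.frame(measure = character(0))
  f <- file.path(outdir, "v_index.csv")
  utils::write.csv(vt, f, row.names = FALSE, quote = FALSE)
  written <- c(written, f)

  if (!is.null(summaries)) {
    if (is.data.frame(summaries)) summaries <- list(summaries)
    sm <- do.call(rbind, summaries)
    num <- vapply(sm, is.numeric, logical(1))
    sm[num] <- lapply(sm[num], function(x) ifelse(is.na(x), "NA", fmt(x)))
    f <- file.path(outdir, "summary.csv")
    utils::write.csv(sm, f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }

  if (isTRUE(plot) && length(trajs)) {
    if (requireNamespace("ggplot2", quietly = TRUE)) {
      f <- file.path(outdir, "s_curve.png")
      p <- plot_s_curves(trajs)
      ggplot2::ggsave(f, p, width = 7, height = 5, dpi = 150)
      written <- c(written, f)
    } else {
      message("ggplot2 not available; skipping s_curve.png")
    }
  }
  invisible(written)
}

#' Plot largest-component curves S(q) for a set of trajectories
#'
#' @param trajectories list of `attack_trajectory` objects.
#' @param q_grid removal fractions at which to evaluate the curves.
#' @return a ggplot object.
#' @export
plot_s_curves <- function(trajectories, q_grid = seq(0, 1, by = 0.01)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_s_curves() requires the ggplot2 package", call. = FALSE)
  }
  trajs <- flatten_trajectories(trajectories)
  df <- do.call(rbind, lapply(trajs, function(tr) {
    cv <- s_curve(tr, q_grid)
    cv$strategy <- if (tr$mode == "random") "random" else
      paste(tr$mode, tr$measure)
    cv
  }))
  agg <- stats::aggregate(S ~ q + strategy, data = df, FUN = mean)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$q, y = .data$S,
                                    colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fraction of vertices removed, q",
                  y = "relative largest component, S(q)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
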