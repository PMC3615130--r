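# Batch driver and command-line interface.

all_strategies <- c("degree", "betweenness", "closeness", "eigenvector", "random")

#' Run a full attack suite on one network
#'
#' Attacks the same graph with each requested strategy and collects the
#' trajectories and robustness indices. The `"random"` strategy always uses
#' uniformly random removal (averaged over `reps` permutations) regardless of
#' `mode`. Each strategy gets its own sub-seed derived from `seed`, so the
#' result for a given strategy does not depend on which others were run.
#'
#' @param g a nonempty graph.
#' @param measures subset of `c("degree", "betweenness", "closeness",
#'   "eigenvector", "random")`.
#' @param mode `"simultaneous"` or `"sequential"` (for the centrality
#'   strategies).
#' @param seed RNG seed.
#' @param reps repetitions for the random strategy.
#' @return an `attack_suite`: list with `trajectories` (named list, one
#'   element per strategy; the random element is itself a list of
#'   repetitions) and `results` (data frame with `measure`, `mode`,
#'   `r_index`, `v_index`).
#' @examples
#' g <- growing_random(300, 2, seed = 1)
#' suite <- attack_suite(g, c("degree", "random"), seed = 1, reps = 3)
#' suite$results
#' @export
attack_suite <- function(g, measures = all_strategies,
                         mode = c("simultaneous", "sequential"),
                         seed = NULL, reps = 10L) {
  mode <- match.arg(mode)
  measures <- match.arg(measures, all_strategies, several.ok = TRUE)
  sub_seed <- function(i) if (is.null(seed)) NULL else as.integer(seed) + i
  trajectories <- list()
  rows <- list()
  for (i in seq_along(measures)) {
    ms <- measures[[i]]
    tr <- if (ms == "random") {
      random_attack(g, seed = sub_seed(i), reps = reps)
    } else if (mode == "simultaneous") {
      simultaneous_attack(g, ms, seed = sub_seed(i))
    } else {
      sequential_attack(g, ms, seed = sub_seed(i))
    }
    rob <- robustness(tr)
    trajectories[[ms]] <- tr
    rows[[i]] <- data.frame(measure = ms,
                            mode = if (ms == "random") "random" else mode,
                            r_index = rob$r_index, v_index = rob$v_index)
  }
  structure(list(trajectories = trajectories, results = do.call(rbind, rows)),
            class = "attack_suite")
}

#' @export
print.attack_suite <- function(x, ...) {
  cat("<attack_suite>\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}

# Model-network families, as named in the batch interface.
build_model <- function(model, n, mean_degree, target_c = NULL, target_r = NULL,
                        seed = NULL) {
  if (mean_degree %% 2 != 0 || mean_degree < 2) {
    stop("`mean-degree` must be an even integer >= 2 (growth adds m = k/2 edges per vertex)",
         call. = FALSE)
  }
  m <- as.integer(mean_degree / 2)
  switch(model,
    power_law = barabasi_albert(n, m, seed = seed),
    exponential = growing_random(n, m, seed = seed),
    clustered = {
      if (is.null(target_c)) stop("clustered model needs --target-c", call. = FALSE)
      calibrate_holme_kim(n, m, target_c, seed = seed)$graph
    },
    assortative = {
      if (is.null(target_r)) stop("assortative model needs --target-r", call. = FALSE)
      # a scale-free realisation dominated by one huge hub may not be able to
      # reach a strongly assortative target at all; draw a fresh realisation
      # (next derived seed) when that happens
      last_err <- NULL
      for (k in 0:5) {
        g <- barabasi_albert(n, m, seed = if (is.null(seed)) NULL else seed + k)
        g2 <- tryCatch(
          rewire_to_assortativity(g, target_r,
                                  seed = if (is.null(seed)) NULL else seed + 50L + k),
          error = function(e) { last_err <<- e; NULL })
        if (!is.null(g2)) return(g2)
      }
      stop("could not realise the assortative target on six seeds: ",
           conditionMessage(last_err), call. = FALSE)
    },
    stop("unknown model: ", model, call. = FALSE))
}

table1_rows <- function() {
  data.frame(
    row = 1:12,
    model = rep(c("power_law", "exponential", "clustered", "assortative"), each = 3),
    mean_degree = c(4, 6, 8, 4, 6, 8, rep(4, 6)),
    target_c = c(rep(NA, 6), 0.25, 0.5, 0.7, rep(NA, 3)),
    target_r = c(rep(NA, 9), -0.1, 0.1, 0.2)
  )
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", substring(a, 3L))
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  flags
}

flag_num <- function(flags, name, default = NULL) {
  if (is.null(flags[[name]])) return(default)
  as.numeric(flags[[name]])
}

cli_usage <- function() {
  c("usage: netrobust <command> [--flag value ...]",
    "",
    "commands:",
    "  generate         --model power_law|exponential|clustered|assortative",
    "                   --n N --mean-degree K [--target-c C] [--target-r R]",
    "                   --seed S --out FILE.edgelist",
    "  attack           (--model ... | --in FILE [--format edgelist|gml])",
    "                   --measure degree|betweenness|closeness|eigenvector|random|all",
    "                   --mode simultaneous|sequential --seed S [--reps R]",
    "                   [--n N --mean-degree K --target-c C --target-r R]",
    "                   --out DIR [--plot]",
    "  summary          --in FILE [--format edgelist|gml] [--out DIR]",
    "  reproduce-table1 [--row 1..12] [--n N] --seed S --out DIR")
}

cli_load_graph <- function(flags) {
  has_model <- !is.null(flags$model)
  has_in <- !is.null(flags$`in`)
  if (has_model && has_in) stop("give either --model or --in, not both", call. = FALSE)
  if (!has_model && !has_in) stop("one of --model or --in is required", call. = FALSE)
  if (has_in) {
    fmt <- if (is.null(flags$format)) "edgelist" else flags$format
    g <- read_graph_file(flags$`in`, fmt)
    message(sprintf("read %s: N = %d, M = %d", flags$`in`,
                    igraph::vcount(g), igraph::ecount(g)))
    return(g)
  }
  seed <- flag_num(flags, "seed")
  if (is.null(seed)) stop("--seed is required for generated networks", call. = FALSE)
  n <- flag_num(flags, "n", 10000)
  k <- flag_num(flags, "mean_degree", 4)
  message(sprintf("generating %s network: n = %d, mean degree = %d, seed = %d",
                  flags$model, as.integer(n), as.integer(k), as.integer(seed)))
  build_model(flags$model, as.integer(n), k,
              target_c = flag_num(flags, "target_c"),
              target_r = flag_num(flags, "target_r"),
              seed = as.integer(seed))
}

cmd_generate <- function(flags) {
  if (is.null(flags$out)) stop("--out FILE is required", call. = FALSE)
  g <- cli_load_graph(flags)
  write_graph_file(g, flags$out)
  message("wrote ", flags$out)
  0L
}

cmd_attack <- function(flags) {
  if (is.null(flags$out)) stop("--out DIR is required", call. = FALSE)
  g <- cli_load_graph(flags)
  measure <- if (is.null(flags$measure)) "all" else flags$measure
  measures <- if (identical(measure, "all")) all_strategies else measure
  mode <- if (is.null(flags$mode)) "simultaneous" else flags$mode
  seed <- flag_num(flags, "seed")
  if (is.null(seed)) stop("--seed is required", call. = FALSE)
  reps <- as.integer(flag_num(flags, "reps", 10))
  message(sprintf("attack: mode = %s, measures = %s, seed = %d, reps = %d",
                  mode, paste(measures, collapse = ","), as.integer(seed), reps))
  suite <- attack_suite(g, measures, mode, seed = as.integer(seed), reps = reps)
  results <- lapply(names(suite$trajectories),
                    function(ms) robustness(suite$trajectories[[ms]]))
  write_results(suite$trajectories, results, list(network_summary(g)),
                outdir = flags$out, plot = isTRUE(flags$plot))
  message("wrote results to ", flags$out)
  print(suite$results, row.names = FALSE)
  0L
}

cmd_summary <- function(flags) {
  if (is.null(flags$`in`)) stop("--in FILE is required", call. = FALSE)
  fmt <- if (is.null(flags$format)) "edgelist" else flags$format
  g <- read_graph_file(flags$`in`, fmt)
  sm <- network_summary(g)
  if (!is.null(flags$out)) {
    write_results(list(), list(), list(sm), outdir = flags$out)
    message("wrote ", file.path(flags$out, "summary.csv"))
  }
  print(sm, row.names = FALSE)
  0L
}

cmd_reproduce_table1 <- function(flags) {
  if (is.null(flags$out)) stop("--out DIR is required", call. = FALSE)
  seed <- flag_num(flags, "seed")
  if (is.null(seed)) stop("--seed is required", call. = FALSE)
  n <- as.integer(flag_num(flags, "n", 10000))
  if (n != 10000L) {
    message(sprintf(paste0("running at n = %d instead of the reference 10000: ",
                           "V-indices are then only pattern-comparable"), n))
  }
  spec <- table1_rows()
  rows <- if (is.null(flags$row)) spec$row else as.integer(flags$row)
  if (!all(rows %in% spec$row)) stop("--row must be in 1..12", call. = FALSE)
  results <- list()
  for (rw in rows) {
    rowspec <- spec[spec$row == rw, ]
    message(sprintf("row %d: %s (k = %d%s%s)", rw, rowspec$model,
                    rowspec$mean_degree,
                    if (is.na(rowspec$target_c)) "" else
                      sprintf(", C = %.2f", rowspec$target_c),
                    if (is.na(rowspec$target_r)) "" else
                      sprintf(", r = %.2f", rowspec$target_r)))
    g <- build_model(rowspec$model, n, rowspec$mean_degree,
                     target_c = if (is.na(rowspec$target_c)) NULL else rowspec$target_c,
                     target_r = if (is.na(rowspec$target_r)) NULL else rowspec$target_r,
                     seed = as.integer(seed) + rw)
    suite <- attack_suite(g, all_strategies, "simultaneous",
                          seed = as.integer(seed) + 100L * rw)
    df <- suite$results
    df$row <- rw
    results[[length(results) + 1L]] <- df
  }
  out <- do.call(rbind, results)
  dir.create(flags$out, showWarnings = FALSE, recursive = TRUE)
  out$r_index <- sprintf("%.6f", out$r_index)
  out$v_index <- sprintf("%.6f", out$v_index)
  f <- file.path(flags$out, "table1.csv")
  utils::write.csv(out[, c("row", "measure", "mode", "r_index", "v_index")],
                   f, row.names = FALSE, quote = FALSE)
  message("wrote ", f)
  0L
}

#' Command-line entry point
#'
#' Drives the whole pipeline from a character vector of arguments (as a
#' shell would supply them). Subcommands: `generate`, `attack`, `summary`,
#' `reproduce-table1`. Returns an exit code rather than calling `quit()`, so
#' it can be tested in-process; the installed script
#' `system.file("cli", "netrobust.R", package = "netrobust")` wraps it for
#' shell use.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(args) == 0L || args[[1L]] %in% c("-h", "--help", "help")) {
      writeLines(cli_usage())
      return(invisible(0L))
    }
    cmd <- args[[1L]]
    flags <- parse_flags(args[-1L])
    switch(cmd,
           "generate" = cmd_generate(flags),
           "attack" = cmd_attack(flags),
           "summary" = cmd_summary(flags),
           "reproduce-table1" = cmd_reproduce_table1(flags),
           stop("unknown command: ", cmd, call. = FALSE))
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    writeLines(cli_usage())
    1L
  })
  invisible(code)
}
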