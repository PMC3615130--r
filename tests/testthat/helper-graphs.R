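# Edge-list constructors for the standard small graphs used across tests.
# All return plain integer matrices so they stay independent of the package's
# own graph type (tests build graphs through graph_from_edges()).

path_edges <- function(n) cbind(seq_len(n - 1L), 2:n)

cycle_edges <- function(n) rbind(path_edges(n), c(n, 1L))

star_edges <- function(leaves) cbind(1L, 1L + seq_len(leaves))

complete_edges <- function(n) t(utils::combn(n, 2L))

# Erdos-Renyi edge list on vertices 1..n (may leave isolated vertices, which
# is intentional: several tests need them).
random_edges <- function(n, p, seed) {
  all_pairs <- t(utils::combn(n, 2L))
  withr::with_seed(seed, all_pairs[stats::runif(nrow(all_pairs)) < p, , drop = FALSE])
}

random_graph <- function(n, p, seed) {
  graph_from_edges(random_edges(n, p, seed), vertices = seq_len(n))
}
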