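---
title: "Measuring network robustness under targeted vertex removal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring network robustness under targeted vertex removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

Many biological and technological systems -- protein interaction maps, neural
wiring diagrams, power grids, contact networks -- keep functioning only while
their underlying network stays largely connected. `netrobust` quantifies how
quickly that connectivity collapses when vertices are knocked out in a
deliberate order: by degree, eigenvector, closeness or betweenness centrality,
or uniformly at random.

The degradation of a network of initial size $N$ is tracked by
$s(Q)$, the number of vertices in the largest connected component after the
first $Q$ removals, divided by $N$. Two scalar summaries condense a whole
attack:

$$R = \frac{1}{N}\sum_{Q=1}^{N} s(Q), \qquad V = \tfrac{1}{2} - R .$$

$R$ is the size-normalised area under the attack curve; the $1/N$ factor makes
networks of different sizes comparable. Over all graphs and removal schemes
$R$ is maximised by the complete graph, at $(N-1)/2N \to 1/2$, and approaches
its minimum on the star graph under hub-first removal. The vulnerability index
$V$ is defined here as the complement with respect to that large-$N$ supremum:
a network/attack pair with $V$ near $0$ is barely hurt; $V$ near $0.5$ means
immediate collapse. The complement-of-$1/2$ form is an interpretation choice
(the defining display in the originating literature is terse); it is adopted
because it reproduces the published index magnitudes on both the robust and
the fragile end, and because `v_index()` then satisfies the exact identity
`v_index(t) + r_index(t) == 0.5`, which the test suite asserts on every
trajectory it builds.

## Attack modes

* **Simultaneous** (`simultaneous_attack()`): score every vertex once on the
  intact network, then remove vertices in decreasing score order.
* **Sequential** (`sequential_attack()`): recompute the scores on the current
  degraded graph before every single removal and remove the current argmax.
* **Random** (`random_attack()`): remove in a uniformly random order,
  replicated (default 10 permutations) and averaged by `robustness()`.

Ties are broken uniformly at random under the trajectory's seed. The
originating analyses are silent on tie handling; on heavily tied graphs
(complete graphs, the degree-2 bulk of scale-free nets) this is the only
stochastic element of a simultaneous degree attack, so the seed is recorded in
the trajectory object.

Every trajectory records $s(Q)$ after *each* removal, because $R$ sums over
all $Q$; `s_curve()` derives fraction-grid views $S(q) = s(\lceil qN\rceil)$
from that record. For ranked orders the whole trajectory is computed in one
pass by running the removals backwards and merging vertices with a union-find
structure (compiled code), so a full $N = 10\,000$ curve costs well under a
second.

## Centrality measures and their conventions

* **Degree**: the neighbour count $k_i$.
* **Eigenvector**: the dominant eigenvector of the adjacency matrix
  (non-negative by Perron-Frobenius), computed by power iteration on $A + I$
  -- the shift suppresses the period-2 oscillation that plain iteration
  exhibits on bipartite graphs. Deterministic all-ones start, unit Euclidean
  norm, convergence when successive iterates differ by less than `tol`
  (default $10^{-10}$, max 10000 steps) in the max norm; non-convergence is
  an error. On disconnected graphs the mass concentrates on the component
  with the largest eigenvalue; the other components score near zero, and an
  edgeless graph scores exactly zero everywhere.
* **Closeness**: $1/\ell_i$ with $\ell_i$ the mean geodesic distance from $i$
  to the vertices of its own component, divisor equal to the component size
  $n_c$ (the self-distance contributes zero to the sum). Within a component
  the choice of $n_c$ versus $n_c - 1$ rescales all scores by a common factor
  and cannot change removal order; across components it can, which is why the
  convention is documented here. Isolated vertices score 0.
* **Betweenness**: each geodesic between an unordered pair $\{s, t\}$ carries
  weight $1/g_{st}$; a vertex collects the weights of the geodesics through
  it, endpoints excluded, and cross-component pairs contribute $0/0 := 0$.

Degree, closeness and betweenness scoring are delegated to igraph's compiled
shortest-path machinery (rescaled where needed to the conventions above);
eigenvector scoring is the package's own iteration. The test suite checks all
four against independent brute-force oracles -- exhaustive geodesic
enumeration, a direct BFS closeness formula, and a dense symmetric
eigendecomposition -- exhaustively over all graphs on four labelled vertices
and on samples of five-, six- and seven-vertex graphs.

One practical caveat feeds the attack engine: heavily degraded graphs develop
long path-like components whose leading eigenvalues are nearly degenerate, so
power iteration may not reach $10^{-10}$ in any reasonable number of steps.
Removal ranking only needs a stable argmax, so `sequential_attack()` and
`simultaneous_attack()` fall back to an implicitly restarted Lanczos solve
(ARPACK, via igraph) and, failing that, to the best available iterate. The
exported `eigenvector_centrality()` keeps the strict error semantics.

## The synthetic-network stage

The generators *are* the study inputs, not test fixtures. All three growth
models share one skeleton: start from the complete graph on $m+1$ vertices
(which guarantees every arrival finds $m$ distinct targets -- the originating
description is silent on the seed graph) and attach each arriving vertex to
$m$ distinct existing vertices, giving exactly
$\binom{m+1}{2} + m(n - m - 1)$ edges and mean degree $\approx 2m$.

* `barabasi_albert()` samples targets with probability proportional to
  degree (repeated stub draws with rejection of duplicates): power-law
  degree tail.
* `growing_random()` samples targets uniformly: exponential degree tail.
* `holme_kim()` follows each preferential step, with probability `p_triad`,
  by a triad-formation step to a uniformly chosen neighbour of the previous
  target (falling back to preferential attachment when no eligible neighbour
  exists). Each arrival still contributes exactly $m$ edges, so the edge
  count and degree distribution are essentially unchanged across `p_triad`;
  only the clustering coefficient moves. `calibrate_holme_kim()` bisects
  `p_triad` against the mean clustering of three pilot graphs per probe until
  the target $C$ is matched within `tol` (default 0.02), then returns a
  realisation that itself satisfies the tolerance. At $m = 2$ the achievable
  ceiling is $C \approx 0.74$; higher targets raise an "unreachable" error
  that reports the ceiling.

Defaults mirror the published study conditions: $N = 10\,000$, $m = 2$
(mean degree 4), clustering targets 0.25/0.5/0.7, assortativity targets
$-0.1$ and $+0.2$.

### Degree-preserving rewiring to a target assortativity

`rewire_to_assortativity()` uses the two-edge move of Xulvi-Brunet and
Sokolov: draw two edges with four distinct endpoints, sort the endpoints by
degree, reconnect either assortatively (highest with second highest) or
disassortatively (highest with lowest), and reject any move that would create
a self-loop or duplicate edge. Degrees never change, so the assortativity
coefficient is an exact $O(1)$ function of $\sum_{(u,v) \in E} k_u k_v$,
updated incrementally -- $r$ is exact at every stopping check, not sampled.

How the moves are scheduled matters more than it first appears. Purely greedy
directed moves, stopped the moment $r$ reaches the target, freeze the first
maximally sorted edge configuration encountered; its hub core is atypically
concentrated and its degree-attack vulnerability measurably lower than that
of a mixed configuration with the same $r$ and degree sequence. The sampler
therefore drives $r$ slightly *past* the target (by `overshoot`, default
0.02) and then lets purely random degree-preserving pairings carry $r$ back
down through the target, so the configuration delivered at the target is the
product of unbiased shuffling; a short directed trim pins
$|r - \text{target}| \le$ `tol` (default 0.005). During the directed drive, a
100k-proposal window with no progress triggers a burst of random pairings to
unlock locally-sorted configurations.

Two facts about scale-free realisations at $n = 10\,000$, $m = 2$ discovered
while validating this stage, both consequences of the heavy-tailed hub
distribution:

* a realisation whose largest hub is extreme (degree $\gtrsim 330$) cannot
  reach $r = 0.22$ at all -- the hub's edges are forced onto low-degree
  partners -- and the function then raises the unreachable-target error
  rather than returning a frozen non-representative graph;
* among attainable realisations the degree-attack $V$ at fixed $r = 0.2$
  still varies with the hub weight (sd $\approx 0.04$). Single-realisation
  vulnerability numbers for assortative networks are therefore quoted in this
  package as means over eight independent generate/rewire/attack
  realisations, with unattainable realisations replaced by the next seeded
  one. The disassortative target $-0.1$ is insensitive to all of this.

## Reproducibility and numerical choices

Every stochastic function takes a `seed` and restores the caller's RNG state;
compiled code draws from R's RNG, so a seed fixes the entire pipeline
byte-for-byte (the determinism tests assert identical edge sets and removal
orders across repeated calls). Derived sub-seeds keep strategies independent:
attacking with a different measure never shifts another measure's result.

Problem sizes used by the automated checks: the published-value comparisons
run at the full $N = 10\,000$ for all families (generation, calibration,
rewiring and all five attack strategies are cheap at that size); the
sequential-versus-simultaneous comparison runs at $N = 2\,000$, where the
complete sequential recalculation of all four measures takes a few minutes
and the published full-scale pattern (sequential at least as damaging;
betweenness the strongest sequential strategy) is already unambiguous.
Oracle comparisons run exhaustively at four vertices and on samples up to
seven, where brute-force geodesic enumeration is exact and fast.

## What the synthetic stage does and does not emulate

The generators reproduce the degree-distribution, clustering and
degree-correlation structure that the attack study varies -- they do not
reproduce other features of real networks (community structure, geometric
embedding, motif profiles, directedness, weights). Passing the model-family
checks therefore says the pipeline reproduces the published model-network
results, not that any particular empirical network will behave like a model
network; empirical edge lists or GML files can be read with
`read_graph_file()` and pushed through the identical attack machinery.

## Known limitations

* Sequential attack recomputes scores $N$ times; at $N = 10\,000$ sequential
  betweenness is hours of work on one core. That cost is inherent to the
  definition; the scaled-down comparison above is the intended desk check.
* `eigenvector_centrality()` on graphs whose two leading eigenvalues are
  (nearly) equal -- e.g. two structurally similar components -- converges
  slowly and may error at the strict default tolerance; the attack engine's
  fallback covers the ranking use case.
* The assortative sampler defines "the rewired network at target $r$" as a
  randomly mixed configuration at that $r$; other definitions (e.g. the
  greedy-frozen configuration) are structurally different despite identical
  $r$ and degree sequence, and do not reproduce the published vulnerability
  values.
* GML support covers the common `node [ id ... ]` / `edge [ source ... ]`
  dialect, read-only.
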