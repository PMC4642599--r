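---
title: "Computing interaction probabilities from signal reachability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing interaction probabilities from signal reachability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigreach)
```

## The problem

Interactions in signaling networks are uncertain: whether a signal actually
crosses a given edge depends on the cell type, the condition, and on
inherently stochastic molecular events. A probabilistic network models this
by attaching an existence probability to every directed edge. Those
per-edge probabilities are hard to observe directly — but end-to-end
behavior is not. The transcription levels of a membrane receptor and of a
downstream transcription factor can be measured in the same samples, and
strong coexpression is long-standing evidence that signal flows between
them.

`sigreach` turns that observation into an estimator. Given a directed
network `G = (V, E)`, a set `S` of source genes (receptors), a set `T` of
target genes (reporters), and an empirical reachability matrix `C` whose
entry `C[s, t]` is the absolute Pearson correlation between the expression
of `s` and of `t`, it searches for the edge-probability vector `P` whose
induced signal reachability matrix `R_P` is as close as possible to `C`:
minimize `||C - R_P||`, where `R_P[s, t]` is the probability that at least
one directed path of present edges connects `s` to `t` when each edge `i`
is independently present with probability `P[i]`.

Three ingredients make this workable, and each is exposed as a module:

1. an **exact reachability engine** (`reachability()`,
   `reachability_matrix()`) for the #P-complete two-terminal reliability
   computation,
2. a **genetic algorithm** (`run_ga()`) for the global search over
   `[0, 1]^|E|`, and
3. a **closed-form per-edge hill climber** (`hill_climb()`) that exploits
   the fact that `R_P[s, t]` is affine in any single edge probability.

## The exact engine: xy-polynomials with path/cut collapsing

Each edge `e_i` carries a binomial `p_i x_i + (1 - p_i) y_i`, with `x_i`
meaning "present" and `y_i` "absent". Multiplying the binomials of a
growing edge set yields an *xy-polynomial*: a sum of terms, each fixing a
subset of the processed edges present and the rest absent, with a
coefficient equal to that joint outcome's probability, plus two free
coefficients — `b`, the mass already known to reach the target (`x*`), and
`c`, the mass already cut off (`y*`). After every multiplication the
polynomial is checked: a term whose present edges already contain a
source-to-target path collapses into `b`; a term whose absent edges
already disconnect the pair collapses into `c` (its present edges plus all
unprocessed edges no longer reach the target). Free coefficients absorb
both outcomes of any further multiplication, so `b + c + sum(a_i)` stays
exactly 1. When all edges are processed every term has collapsed, and `b`
is the pair's reachability.

Two implementations of this algorithm coexist deliberately. The exported
`xy_polynomial()` / `multiply_edge()` / `collapse_terms()` functions run it
step by step on a plain list structure, so each mechanism can be inspected
and unit-tested in isolation. The production path (`reachability()` and
everything built on it) runs in compiled code with terms as 64-bit
bitmasks. The test suite holds the two to each other, to a subset
enumeration oracle, and to closed forms on canonical topologies, all at
`1e-12`.

The compiled engine applies two correctness-preserving optimizations:

* **Relevant-edge restriction.** For a pair `(s, t)`, only edges whose
  tail is reachable from `s` and whose head reaches `t` can lie on an
  `s -> t` path; all other edges are excluded before any multiplication.
  They could never satisfy a path or cut test and would only double the
  term count.
* **Breadth-first multiplication order** from the source, so that path and
  cut collapses fire as early as possible. Any order gives the same final
  polynomial (a tested invariant); the order only bounds intermediate
  growth.

Degenerate inputs follow fixed conventions: `s == t` returns 1 (the empty
path), a graph-unreachable target returns 0, and cyclic networks are
handled like any others (path tests are plain graph searches). Two guards
bound resource use: at most 64 relevant edges per pair (the bitmask width)
and a configurable cap of 2×10⁶ live terms, both raising clear errors
rather than exhausting memory. Conservation is asserted after every step
and an error is raised if `b + c + sum(a_i)` drifts from 1 by more than
`1e-9`; in practice the drift is at machine-epsilon scale.

## Phase 1: the genetic algorithm

A candidate solution `psi` assigns a probability to each edge. Its fitness
is

```
F_psi = 1 - ||C - R_psi||_2 / |S x T|,   ||.||_2 = sqrt(sum of squares)
```

which is 1 exactly when `R_psi` reproduces `C`. The signed gap
`g_psi = sum(C - R_psi)` records whether the candidate underestimates
(positive) or overestimates (negative) reachability in aggregate, and it
steers crossover: for each entry, two parents with positive gaps donate the
larger value, two with negative gaps the smaller, and with mixed signs the
entry is drawn from parent 1 with probability `F_1 / (F_1 + F_2)`. A gap
of exactly 0 is treated as positive — zero aggregate bias gives no reason
to shrink entries, and the tie must break deterministically.

Defaults follow the method as published: population 50, per-entry mutation
rate 0.01 (a Bernoulli trial replacing the entry with a fresh uniform
draw), selection keeping the 5 fittest plus 45 fitness-proportional draws
without replacement from the remaining 95. Each generation appends 50
crossover children (each from two *distinct* fitness-proportionally drawn
parents — self-crossover is a no-op child and is redrawn), mutates the
entire doubled population, and selects back to 50. The iteration count has
no principled value — convergence depends on the network — so it is a
parameter with default 100.

One deliberate deviation: the returned solution is the best candidate
*ever archived*, not the best of the final population. The two coincide
unless a late mutation damages the incumbent; the archive is the stronger
guarantee and makes the best-fitness trace non-decreasing by construction.
All randomness flows from a single caller-supplied seed, so a fixed seed
reproduces a run exactly. With every candidate's fitness at 0 (a
measure-zero pathological start), proportional sampling falls back to
uniform rather than dividing by zero.

## Phase 2: closed-form coordinate descent

Reachability is multilinear in the edge probabilities, so holding all
edges but `e` fixed, `R[s, t] = alpha_st + beta_st * p_e`. The engine
obtains `(alpha_st, beta_st)` by *deferring* `e`'s binomial until last:
`alpha_st` is then the reached coefficient `b`, and `beta_st` the summed
mass of the surviving non-free terms — every one of which lacks a path on
its own present edges but gains one when `e` is added (also a tested
property). The error as a function of `p_e` alone,

```
sum over (s, t) of (C[s, t] - alpha_st - beta_st * p_e)^2,
```

is a convex 1-D quadratic with minimizer

```
p_e = sum(beta_st * (C[s, t] - alpha_st)) / sum(beta_st^2),
```

clipped to `[0, 1]` — by convexity the nearest boundary is optimal when
the unconstrained optimum escapes the unit interval. The hill climber
sweeps the edges in ascending index order (any order is valid; a fixed one
makes runs reproducible), applying this update edge by edge. Each update
is exactly non-increasing in the summed squared error, the error is
bounded below by 0, and sweeps stop once a full sweep improves it by less
than `tolerance` (default `1e-9` absolute, with a safety cap of 1000
sweeps).

Two numerical points. First, the quantity *minimized* is the plain sum of
squares while fitness and quality are *reported* with the square root;
the argmin is the same either way, and the reported scale matches the
fitness definition above. Second, an edge with `sum(beta_st^2) = 0`
influences no source-target pair: the objective is constant in it, its
value is left untouched, and it is flagged `non_identifiable` in the
output rather than silently assigned a meaningless number.

## The empirical matrix

`coexpression_matrix()` computes `C[s, t] = |cor(expr[s, ], expr[t, ])|`
over samples. The absolute value is the operative definition throughout:
strong anticorrelation is still evidence of signal flow. Deliberate
policies: rows containing missing values are rejected at load (no silent
pairwise-complete correlations — no imputation policy is assumed),
zero-variance genes are an error by name (their correlation is
undefined), at least 3 samples are required, and each condition (e.g. a
disease subtype) is fit separately from its own samples' submatrix.
Normalization of raw expression is an upstream concern.

## What the synthetic generator emulates — and what it does not

`generate_network()` draws a random DAG, takes sources from its roots and
targets from its sinks, and rejection-samples until every target is
reachable from at least one source — the shape of curated signaling
pathways (receptors upstream, transcription factors downstream), at
configurable size. Curated pathway excerpts are largely acyclic, hence the
DAG default; the engine itself is indifferent to cycles and
`allow_cycles = TRUE` adds them for stress tests.

`generate_instance()` draws ground-truth probabilities i.i.d. uniform on
`[0, 1]` (matching the GA's search prior), computes the exact clean matrix
`C = R_P*`, and optionally adds Gaussian noise clipped to `[0, 1]`. Noise
is added in reachability space because that is what the optimizer
consumes; `simulate_expression()` additionally provides a latent-signal
linear-propagation model for end-to-end tests through the coexpression
path.

What passing on such data shows: that the optimizer recovers reachability
essentially exactly when an exactly-representable `C` exists, and degrades
gracefully under calibrated noise. What it does not show: performance on
real coexpression matrices, which are generally *not* representable as any
`R_P` (correlations are confounded, non-transitive, and noisy in
structured ways no Gaussian captures). Note also that recovery is assessed
in reachability space (quality), never by comparing probability vectors
entrywise: distinct vectors can induce identical reachability matrices, so
`P*` itself is not identifiable.

The package's own desk-scale reference condition, used in the acceptance
test, is a 20-node / 25-edge instance with 3 sources and 3 targets and a
noise-free `C` — small enough for the whole two-phase fit to run in
seconds, large enough that the polynomial engine, both optimizer phases,
and the quality accounting are all genuinely exercised.

## Post-fit analytics

* `reach_quality()` — fitness as a percentage; the headline accuracy
  measure of a fit.
* `probability_entropy()` — entropy (natural log; the base only rescales
  comparisons) of the fitted probabilities over ten bins
  `[0, 0.1), ..., [0.9, 1]`, the last bin closed. High entropy means the
  method spreads probabilities across the spectrum instead of crowding a
  few values.
* `condition_distances()` — Euclidean distances between the
  edge-probability vectors of conditions sharing one network, plus each
  condition's mean distance to the others.
* `outstanding_interactions()` — for each edge, mean and standard
  deviation of its probability across all conditions; a (condition, edge)
  pair is flagged when its value is at least 2 standard deviations from
  the mean, and the endpoints of flagged edges form the condition's
  outstanding gene set `L` (the natural input to gene-set enrichment
  tools). The *population* (N-denominator) standard deviation is used —
  the conditions at hand are the whole population of interest, not a
  sample — and `sigma = 0` edges are never flagged (all values equal, so
  none deviates). The statistics are always taken over all conditions,
  the flagged condition included.
* `node_centrality()` — each gene's contribution to reachability: the
  total drop in the source-target matrix when the gene's incident edges
  are removed, pairs involving the gene itself excluded. Non-negative by
  monotonicity, zero off all source-target paths. This removal definition
  is one direct operationalization of "contribution to reachability" and
  is labeled removal centrality in the output; other centrality
  definitions for probabilistic networks exist and would rank nodes
  differently.

## Worked example

```{r example}
net <- generate_network(
  n_nodes = 12, n_edges = 16, n_sources = 3, n_targets = 3, seed = 7
)
inst <- generate_instance(net, noise_sd = 0, seed = 8)
fit <- fit_probabilities(net, inst$C_clean, ga_iterations = 30, seed = 9)
glance(fit)
tidy(fit)
probability_entropy(fit$psi)
```

```{r plot, fig.width = 6, fig.height = 3.5}
autoplot(fit)
```

## Limitations

* The per-pair polynomial is capped at 64 relevant edges; dense networks
  where a single source-target pair spans more need decomposition or a
  Monte-Carlo approach, which this package deliberately does not provide
  (the engine's exactness is the point).
* The GA's iteration count is a tuning knob, not a convergence guarantee;
  the hill climber guarantees only a coordinate-wise local optimum.
* Absolute correlation is a coarse reachability proxy: it cannot separate
  direct regulation from confounding, and the fit inherits that
  limitation regardless of optimizer accuracy.
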