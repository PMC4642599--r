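#' Exact signal reachability between a source and a target
#'
#' Computes the probability that a signal propagates from `source` to
#' `target` when every edge `i` is independently present with probability
#' `probabilities[i]`: the probability that at least one directed path of
#' present edges connects the pair (two-terminal reliability, a
#' #P-complete problem). `method = "collapse"` runs the exact
#' xy-polynomial engine with path/cut collapsing (see [xy_polynomial()] for
#' the mechanics); `method = "enumerate"` sums over all `2^|E|` edge
#' subsets and is the independent oracle, refused above 20 edges.
#'
#' `source == target` returns 1 by the empty-path convention; a target with
#' no directed path from the source returns 0.
#'
#' @param network A [signal_network()].
#' @param source,target Node identifiers.
#' @param probabilities Optional probability vector in edge order; defaults
#'   to the network's own probabilities, which must then be fully set.
#' @param method `"collapse"` (exact engine, default) or `"enumerate"`
#'   (subset enumeration, `|E| <= 20`).
#' @param term_cap Abort if the collapsed polynomial ever holds more than
#'   this many terms (guards memory on adversarial topologies).
#' @return A single probability.
#' @examples
#' net <- fixture_network("diamond")
#' reachability(net, "s", "t", probabilities = rep(0.5, 4)) # 0.4375
#' @export
reachability <- function(network, source, target, probabilities = NULL,
                         method = c("collapse", "enumerate"),
                         term_cap = 2e6) {
  stopifnot(inherits(network, "signal_network"))
  method <- match.arg(method)
  probabilities <- resolve_probabilities(network, probabilities)
  s <- node_index(network, source)
  t <- node_index(network, target)
  if (method == "enumerate") {
    return(enumerate_reachability(network, probabilities, s, t))
  }
  ef <- match(network$edges$from, network$nodes) - 1L
  et <- match(network$edges$to, network$nodes) - 1L
  cpp_reachability(ef, et, length(network$nodes), probabilities,
    s - 1L, t - 1L,
    term_cap = term_cap
  )
}

# subset-enumeration oracle: sum over all 2^|E| edge subsets of the product
# of present/absent probabilities times the path indicator
enumerate_reachability <- function(network, probabilities, s, t) {
  m <- n_edges(network)
  if (m > 20) {
    stop("subset enumeration refused for more than 20 edges", call. = FALSE)
  }
  if (s == t) {
    return(1)
  }
  ef <- match(network$edges$from, network$nodes)
  et <- match(network$edges$to, network$nodes)
  total <- 0
  for (code in 0:(2^m - 1)) {
    present <- which(bitwAnd(code, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    w <- prod(probabilities[present]) * prod(1 - probabilities[setdiff(seq_len(m), present)])
    if (w == 0) next
    if (edge_subset_reaches(ef, et, length(network$nodes), present, s, t)) {
      total <- total + w
    }
  }
  total
}

#' Signal reachability matrix for all declared source-target pairs
#'
#' Computes the `|S| x |T|` matrix `R_P` whose `(s, t)` entry is
#' [reachability()] from source `s` to target `t`, each pair evaluated
#' independently by the exact engine.
#'
#' @inheritParams reachability
#' @return A numeric matrix with source row names and target column names.
#' @export
reachability_matrix <- function(network, probabilities = NULL, term_cap = 2e6) {
  stopifnot(inherits(network, "signal_network"))
  if (length(network$sources) == 0 || length(network$targets) == 0) {
    stop("network must declare non-empty source and target sets", call. = FALSE)
  }
  probabilities <- resolve_probabilities(network, probabilities)
  ef <- match(network$edges$from, network$nodes) - 1L
  et <- match(network$edges$to, network$nodes) - 1L
  R <- cpp_reach_matrix(
    ef, et, length(network$nodes), probabilities,
    node_index(network, network$sources) - 1L,
    node_index(network, network$targets) - 1L,
    term_cap
  )
  dimnames(R) <- list(network$sources, network$targets)
  R
}

#' Affine decomposition of reachability in one deferred edge
#'
#' With every edge binomial multiplied in except that of `edge`, pair
#' reachability is affine in that edge's probability:
#' `R(p_e) = alpha + beta * p_e`, where `alpha` is the reached coefficient
#' of the deferred polynomial and `beta` the total mass of its surviving
#' non-free terms. This is the workhorse of the per-edge closed-form
#' optimizer ([optimal_edge_probability()]).
#'
#' @inheritParams reachability
#' @param edge Edge index (1-based, edge order) whose binomial is deferred.
#' @return A named list with `alpha` and `beta`, satisfying
#'   `0 <= alpha <= alpha + beta <= 1`.
#' @export
linear_coefficients <- function(network, edge, source, target,
                                probabilities = NULL, term_cap = 2e6) {
  stopifnot(inherits(network, "signal_network"))
  edge <- as.integer(edge)
  if (edge < 1 || edge > n_edges(network)) {
    stop(sprintf("edge index %d outside 1..%d", edge, n_edges(network)), call. = FALSE)
  }
  probabilities <- resolve_probabilities(network, probabilities)
  s <- node_index(network, source)
  t <- node_index(network, target)
  ef <- match(network$edges$from, network$nodes) - 1L
  et <- match(network$edges$to, network$nodes) - 1L
  ab <- cpp_linear(
    ef, et, length(network$nodes), probabilities,
    s - 1L, t - 1L, edge - 1L, term_cap
  )
  list(alpha = ab[1], beta = ab[2])
}

# alpha/beta matrices over all declared pairs for one deferred edge
linear_pair_matrices <- function(network, probabilities, edge, term_cap = 2e6) {
  ef <- match(network$edges$from, network$nodes) - 1L
  et <- match(network$edges$to, network$nodes) - 1L
  res <- cpp_linear_pairs(
    ef, et, length(network$nodes), probabilities,
    node_index(network, network$sources) - 1L,
    node_index(network, network$targets) - 1L,
    as.integer(edge) - 1L, term_cap
  )
  dimnames(res$alpha) <- list(network$sources, network$targets)
  dimnames(res$beta) <- list(network$sources, network$targets)
  res
}
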