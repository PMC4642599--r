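#' Generate a random source-target signaling network
#'
#' Draws a random directed acyclic graph with the requested node and edge
#' counts, designates sources among its roots (in-degree 0) and targets
#' among its sinks (out-degree 0), and rejection-samples until every target
#' is reachable from at least one source. Used to emulate the shape of
#' curated signaling pathways (receptors at the top, transcription factors
#' at the bottom) at configurable size; it makes no attempt to mimic any
#' specific pathway's topology.
#'
#' @param n_nodes,n_edges Size of the graph.
#' @param n_sources,n_targets Number of source and target nodes
#'   (`n_sources + n_targets <= n_nodes`).
#' @param seed Optional integer seed for reproducibility.
#' @param allow_cycles Sample edges over all ordered node pairs instead of
#'   respecting a topological order (stress-testing the engine on cyclic
#'   graphs).
#' @param max_tries Attempts before giving up on the constraints.
#' @return A [signal_network()] with unset probabilities.
#' @examples
#' generate_network(8, 10, n_sources = 2, n_targets = 2, seed = 1)
#' @export
generate_network <- function(n_nodes, n_edges, n_sources = 1, n_targets = 1,
                             seed = NULL, allow_cycles = FALSE,
                             max_tries = 1000) {
  stopifnot(n_nodes >= 2, n_edges >= 1, n_sources >= 1, n_targets >= 1)
  if (n_sources + n_targets > n_nodes) {
    stop("`n_sources + n_targets` cannot exceed `n_nodes`", call. = FALSE)
  }
  max_pairs <- if (allow_cycles) n_nodes * (n_nodes - 1) else choose(n_nodes, 2)
  if (n_edges > max_pairs) {
    stop(sprintf("at most %d distinct directed edges are possible", max_pairs),
      call. = FALSE
    )
  }
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      generate_network(n_nodes, n_edges, n_sources, n_targets,
        seed = NULL, allow_cycles = allow_cycles, max_tries = max_tries
      )
    ))
  }

  nodes <- sprintf("n%02d", seq_len(n_nodes))
  for (try in seq_len(max_tries)) {
    ord <- sample(nodes)
    if (allow_cycles) {
      pairs <- expand.grid(i = seq_len(n_nodes), j = seq_len(n_nodes))
      pairs <- pairs[pairs$i != pairs$j, ]
    } else {
      idx <- utils::combn(n_nodes, 2)
      pairs <- data.frame(i = idx[1, ], j = idx[2, ])
    }
    take <- pairs[sample.int(nrow(pairs), n_edges), ]
    from <- ord[take$i]
    to <- ord[take$j]

    indeg <- table(factor(to, levels = nodes))
    outdeg <- table(factor(from, levels = nodes))
    used <- nodes %in% c(from, to)
    roots <- nodes[used & indeg == 0]
    sinks <- nodes[used & outdeg == 0]
    if (length(roots) < n_sources || length(setdiff(sinks, roots)) < n_targets) next

    sources <- sample(roots, n_sources)
    targets <- sample(setdiff(sinks, sources), n_targets)
    net <- signal_network(data.frame(from = from, to = to),
      sources = sources, targets = targets, nodes = nodes
    )
    ef <- match(from, nodes)
    et <- match(to, nodes)
    ok <- vapply(targets, function(tg) {
      any(vapply(sources, function(s) {
        edge_subset_reaches(
          ef, et, n_nodes, seq_len(n_edges),
          match(s, nodes), match(tg, nodes)
        )
      }, logical(1)))
    }, logical(1))
    if (all(ok)) {
      return(net)
    }
  }
  stop(sprintf(
    "could not satisfy the connectivity constraints in %d tries; relax the parameters",
    max_tries
  ), call. = FALSE)
}

#' Generate a synthetic instance with known ground truth
#'
#' Draws a ground-truth probability vector `P*` i.i.d. uniform on `[0, 1]`,
#' computes the exact reachability matrix it induces (`C_clean`), and
#' optionally perturbs it with clipped Gaussian noise in reachability
#' space (`C_noisy`). Fitting against `C_clean` should recover the clean
#' reachability matrix essentially exactly (the probability vector itself
#' is generally not identifiable: distinct vectors can induce the same
#' reachability matrix).
#'
#' @param network A [signal_network()] with declared sources and targets.
#' @param noise_sd Standard deviation of the Gaussian perturbation added to
#'   each entry of `C_clean` (default 0: no noise).
#' @param seed Optional integer seed.
#' @param term_cap Passed to the reachability engine.
#' @return An object of class `synthetic_instance`: list with `network`
#'   (probabilities set to the ground truth), `ground_truth`, `C_clean`,
#'   `C_noisy` (equal to `C_clean` when `noise_sd = 0`) and `noise_sd`.
#' @export
generate_instance <- function(network, noise_sd = 0, seed = NULL,
                              term_cap = 2e6) {
  stopifnot(inherits(network, "signal_network"), noise_sd >= 0)
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      generate_instance(network, noise_sd, seed = NULL, term_cap = term_cap)
    ))
  }
  p_star <- stats::runif(n_edges(network))
  C_clean <- reachability_matrix(network, probabilities = p_star, term_cap = term_cap)
  C_noisy <- C_clean
  if (noise_sd > 0) {
    C_noisy <- C_clean + matrix(
      stats::rnorm(length(C_clean), sd = noise_sd),
      nrow = nrow(C_clean)
    )
    C_noisy[C_noisy < 0] <- 0
    C_noisy[C_noisy > 1] <- 1
  }
  structure(
    list(
      network = set_probabilities(network, p_star),
      ground_truth = p_star,
      C_clean = C_clean,
      C_noisy = C_noisy,
      noise_sd = noise_sd
    ),
    class = "synthetic_instance"
  )
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat(sprintf(
    "<synthetic_instance> %d nodes, %d edges, %d source(s) x %d target(s), noise sd %g\n",
    n_nodes(x$network), n_edges(x$network),
    length(x$network$sources), length(x$network$targets), x$noise_sd
  ))
  invisible(x)
}

#' Canonical toy networks with closed-form reachability
#'
#' Small named topologies whose source-to-target reachability has a
#' closed form, used throughout the tests as analytic oracles:
#' \describe{
#'   \item{single_edge}{`s -> t`; reachability `p1`.}
#'   \item{series}{`s -> m -> t`; `p1 * p2`.}
#'   \item{parallel}{two parallel `s -> t` edges; `1 - (1-p1)(1-p2)`
#'     (constructed with `allow_parallel`).}
#'   \item{diamond}{`s -> a -> t` and `s -> b -> t`;
#'     `1 - (1 - p1 p2)(1 - p3 p4)`.}
#'   \item{bridge}{the five-edge Wheatstone bridge `s -> a`, `s -> b`,
#'     `a -> b`, `a -> t`, `b -> t`; closed form by conditioning on the
#'     bridge edge `a -> b`.}
#' }
#'
#' @param name One of `"single_edge"`, `"series"`, `"parallel"`,
#'   `"diamond"`, `"bridge"`.
#' @param probabilities Optional probability vector to set on the returned
#'   network (in the edge order listed above).
#' @return A [signal_network()] with source `"s"` and target `"t"`.
#' @export
fixture_network <- function(name, probabilities = NULL) {
  edges <- switch(name,
    single_edge = data.frame(from = "s", to = "t"),
    series = data.frame(from = c("s", "m"), to = c("m", "t")),
    parallel = data.frame(from = c("s", "s"), to = c("t", "t")),
    diamond = data.frame(
      from = c("s", "a", "s", "b"),
      to = c("a", "t", "b", "t")
    ),
    bridge = data.frame(
      from = c("s", "s", "a", "a", "b"),
      to = c("a", "b", "b", "t", "t")
    ),
    stop(sprintf("unknown fixture '%s'", name), call. = FALSE)
  )
  net <- signal_network(edges,
    sources = "s", targets = "t",
    allow_parallel = identical(name, "parallel")
  )
  if (!is.null(probabilities)) net <- set_probabilities(net, probabilities)
  net
}

#' Simulate expression data consistent with a probabilistic network
#'
#' A light-weight generative model for end-to-end tests of the
#' coexpression path: each source gene receives an independent standard
#' normal latent signal per sample; every other gene's expression is the
#' reachability-weighted sum of the source signals (signal attenuates with
#' the probability of reaching the gene) plus Gaussian measurement noise.
#' Genes that are strongly reachable from a source therefore correlate
#' strongly with it. This emulates correlated transcription, not any
#' mechanistic transcriptional dynamics.
#'
#' @param instance A `synthetic_instance` (ground-truth probabilities are
#'   used as the propagation weights).
#' @param n_samples Number of samples (columns) to simulate.
#' @param noise_sd Measurement noise standard deviation (default 0.1).
#' @param seed Optional integer seed.
#' @return A numeric matrix, genes x samples, with node row names.
#' @export
simulate_expression <- function(instance, n_samples = 50, noise_sd = 0.1,
                                seed = NULL) {
  stopifnot(inherits(instance, "synthetic_instance"), n_samples >= 3)
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      simulate_expression(instance, n_samples, noise_sd, seed = NULL)
    ))
  }
  net <- instance$network
  nodes <- net$nodes
  p <- instance$ground_truth
  latent <- matrix(stats::rnorm(length(net$sources) * n_samples),
    nrow = length(net$sources), dimnames = list(net$sources, NULL)
  )
  expr <- matrix(0, nrow = length(nodes), ncol = n_samples,
    dimnames = list(nodes, sprintf("sample%03d", seq_len(n_samples))))
  for (v in nodes) {
    if (v %in% net$sources) {
      expr[v, ] <- latent[v, ]
      next
    }
    w <- vapply(net$sources, function(s) {
      reachability(net, s, v, probabilities = p)
    }, numeric(1))
    expr[v, ] <- drop(w %*% latent)
  }
  expr + matrix(stats::rnorm(length(expr), sd = noise_sd), nrow = nrow(expr))
}
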