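#' Closed-form optimal probability for a single edge
#'
#' Holding every other edge fixed, pair reachability is affine in the
#' probability of `edge` (see [linear_coefficients()]):
#' `R[s, t] = alpha_st + beta_st * p_e`. The sum of squared differences to
#' the empirical matrix is therefore a convex 1-D quadratic in `p_e`, whose
#' unconstrained minimizer is
#' `p_e = sum(beta_st * (C[s, t] - alpha_st)) / sum(beta_st^2)`,
#' clipped to `[0, 1]` (by convexity the nearest boundary is optimal when
#' the minimizer falls outside). An edge that influences no source-target
#' pair has all `beta_st = 0`; its probability is left unchanged, as the
#' objective is constant in it (the edge is non-identifiable).
#'
#' @param network A [signal_network()].
#' @param C Empirical reachability matrix.
#' @param edge Edge index to optimize.
#' @param psi Current probability vector (entries other than `edge` are held
#'   fixed).
#' @param term_cap Passed to the reachability engine.
#' @return The optimal probability for `edge` in `[0, 1]`.
#' @export
optimal_edge_probability <- function(network, C, edge, psi, term_cap = 2e6) {
  stopifnot(inherits(network, "signal_network"))
  edge <- as.integer(edge)
  if (edge < 1 || edge > n_edges(network)) {
    stop(sprintf("edge index %d outside 1..%d", edge, n_edges(network)), call. = FALSE)
  }
  C <- align_matrix(C, network)
  psi <- resolve_probabilities(network, psi)
  lin <- linear_pair_matrices(network, psi, edge, term_cap)
  b2 <- sum(lin$beta^2)
  if (b2 == 0) {
    return(psi[edge])
  }
  p <- sum(lin$beta * (C - lin$alpha)) / b2
  min(1, max(0, p))
}

#' Phase 2: local optimization by per-edge hill climbing
#'
#' Starting from `psi0`, sweeps over the edges in ascending index order and
#' replaces each probability with its closed-form optimum
#' ([optimal_edge_probability()]), which can only decrease the sum of
#' squared differences `SSE = sum((C - R)^2)`. Sweeps repeat until a full
#' sweep improves the SSE by less than `tolerance` (or `max_sweeps` is
#' reached). Minimizing the SSE and minimizing its square root have the
#' same argmin; reported fitness and quality apply the root.
#'
#' @inheritParams optimal_edge_probability
#' @param psi0 Starting probability vector (e.g. the phase-1 result).
#' @param tolerance Minimum SSE improvement per full sweep to continue
#'   (default 1e-9).
#' @param max_sweeps Safety cap on the number of sweeps (default 1000).
#' @return An object of class `hill_climb_result`: list with the final
#'   `psi`, `sse`, `fitness`, `quality`, `gap`, `R`, the number of `sweeps`
#'   run, a `converged` flag, `sse_trace` (SSE after every single-edge
#'   update; non-increasing), and `non_identifiable` (logical per edge,
#'   `TRUE` where no source-target pair responds to the edge).
#' @export
hill_climb <- function(network, C, psi0, tolerance = 1e-9, max_sweeps = 1000,
                       term_cap = 2e6) {
  stopifnot(inherits(network, "signal_network"), tolerance > 0)
  C <- align_matrix(C, network)
  psi <- resolve_probabilities(network, psi0)
  m <- n_edges(network)

  R <- reachability_matrix(network, probabilities = psi, term_cap = term_cap)
  sse <- sum((C - R)^2)
  sse_trace <- numeric(0)
  non_identifiable <- logical(m)
  sweeps <- 0L
  converged <- FALSE

  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    sse_at_sweep_start <- sse
    for (e in seq_len(m)) {
      lin <- linear_pair_matrices(network, psi, e, term_cap)
      b2 <- sum(lin$beta^2)
      if (b2 == 0) {
        non_identifiable[e] <- TRUE
        sse_trace <- c(sse_trace, sse)
        next
      }
      non_identifiable[e] <- FALSE
      p <- sum(lin$beta * (C - lin$alpha)) / b2
      p <- min(1, max(0, p))
      # both SSE values come from the same affine decomposition, so the
      # update is exactly non-increasing by convexity
      sse <- sum((C - lin$alpha - lin$beta * p)^2)
      psi[e] <- p
      sse_trace <- c(sse_trace, sse)
    }
    if (sse_at_sweep_start - sse < tolerance) {
      converged <- TRUE
      break
    }
  }

  R <- reachability_matrix(network, probabilities = psi, term_cap = term_cap)
  structure(
    list(
      psi = psi,
      sse = sum((C - R)^2),
      fitness = solution_fitness(C, R),
      quality = reach_quality(C, R),
      gap = solution_gap(C, R),
      R = R,
      sweeps = sweeps,
      converged = converged,
      sse_trace = sse_trace,
      non_identifiable = non_identifiable
    ),
    class = "hill_climb_result"
  )
}

#' @export
print.hill_climb_result <- function(x, ...) {
  cat(sprintf(
    "<hill_climb_result> %d edges, SSE %.3e, quality %.2f%%, %d sweep(s)%s\n",
    length(x$psi), x$sse, x$quality, x$sweeps,
    if (x$converged) " (converged)" else " (sweep cap reached)"
  ))
  invisible(x)
}
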