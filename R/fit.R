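#' Fit interaction probabilities to an empirical reachability matrix
#'
#' The full two-phase pipeline: a genetic algorithm ([run_ga()]) searches
#' the space of edge-probability vectors globally, then per-edge closed-form
#' hill climbing ([hill_climb()]) refines the best solution until no single
#' edge probability can be changed without increasing the reachability
#' error. The empirical matrix `C` is typically the absolute source-target
#' coexpression ([coexpression_matrix()]) or, for synthetic studies, a
#' reachability matrix from known ground truth
#' ([generate_instance()]).
#'
#' @inheritParams run_ga
#' @param ga_iterations Generations for the global phase (default 100).
#' @param tolerance,max_sweeps Convergence controls for the local phase.
#' @param skip_ga Skip phase 1 and hill-climb from `psi0` (or a uniform
#'   random start when `psi0` is `NULL`).
#' @param psi0 Optional starting vector for the local phase when
#'   `skip_ga = TRUE`.
#' @return An object of class `signal_fit`: list with the fitted `network`
#'   (probabilities set), `psi`, `fitness`, `quality` (percent), `gap`,
#'   `sse`, `R`, `C`, `ga` (the `ga_result`, or `NULL` when skipped),
#'   `local` (the `hill_climb_result`) and `seed`. Supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' inst <- generate_instance(
#'   generate_network(8, 9, n_sources = 2, n_targets = 2, seed = 4),
#'   seed = 4
#' )
#' fit <- fit_probabilities(inst$network, inst$C_clean,
#'   ga_iterations = 10, seed = 1
#' )
#' glance(fit)
#' }
#' @export
fit_probabilities <- function(network, C, ga_iterations = 100,
                              population_size = 50, mutation_rate = 0.01,
                              n_elite = 5, tolerance = 1e-9,
                              max_sweeps = 1000, skip_ga = FALSE,
                              psi0 = NULL, seed = NULL, term_cap = 2e6) {
  stopifnot(inherits(network, "signal_network"))
  C <- align_matrix(C, network)
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      fit_probabilities(network, C, ga_iterations, population_size,
        mutation_rate, n_elite, tolerance, max_sweeps, skip_ga, psi0,
        seed = NULL, term_cap = term_cap
      )
    ))
  }

  ga <- NULL
  if (skip_ga) {
    start <- if (is.null(psi0)) stats::runif(n_edges(network)) else resolve_probabilities(network, psi0)
  } else {
    ga <- run_ga(network, C,
      iterations = ga_iterations, population_size = population_size,
      mutation_rate = mutation_rate, n_elite = n_elite, term_cap = term_cap
    )
    start <- ga$psi
  }
  local <- hill_climb(network, C, start,
    tolerance = tolerance,
    max_sweeps = max_sweeps, term_cap = term_cap
  )

  structure(
    list(
      network = set_probabilities(network, local$psi),
      psi = local$psi,
      fitness = local$fitness,
      quality = local$quality,
      gap = local$gap,
      sse = local$sse,
      R = local$R,
      C = C,
      ga = ga,
      local = local,
      seed = seed
    ),
    class = "signal_fit"
  )
}

#' @export
print.signal_fit <- function(x, ...) {
  cat(sprintf(
    "<signal_fit> %d edges, quality %.2f%% (fitness %.6f, gap %+.4f)\n",
    length(x$psi), x$quality, x$fitness, x$gap
  ))
  cat(sprintf(
    "  phase 1: %s; phase 2: %d sweep(s)%s\n",
    if (is.null(x$ga)) "skipped" else sprintf("%d generation(s)", nrow(x$ga$trace)),
    x$local$sweeps, if (x$local$converged) ", converged" else ""
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted probability assignment
#'
#' @param x A `signal_fit` object.
#' @param ... Unused.
#' @return One row per edge: `edge` (index), `from`, `to`, `probability`,
#'   and `identifiable` (`FALSE` where no declared source-target pair
#'   responds to the edge, so its value is arbitrary).
#' @export
tidy.signal_fit <- function(x, ...) {
  tibble::tibble(
    edge = seq_along(x$psi),
    from = x$network$edges$from,
    to = x$network$edges$to,
    probability = x$psi,
    identifiable = !x$local$non_identifiable
  )
}

#' @rdname tidy.signal_fit
#' @return `glance()`: a one-row tibble with `fitness`, `quality`, `gap`,
#'   `sse`, `ga_generations`, `sweeps` and `converged`.
#' @export
glance.signal_fit <- function(x, ...) {
  tibble::tibble(
    fitness = x$fitness,
    quality = x$quality,
    gap = x$gap,
    sse = x$sse,
    ga_generations = if (is.null(x$ga)) 0L else nrow(x$ga$trace),
    sweeps = x$local$sweeps,
    converged = x$local$converged
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the optimization trajectory of a fit
#'
#' Shows the archived best fitness per genetic-algorithm generation,
#' with the final (post hill-climbing) fitness as a horizontal reference.
#'
#' @param object A `signal_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signal_fit <- function(object, ...) {
  if (is.null(object$ga)) {
    df <- tibble::tibble(update = seq_along(object$local$sse_trace),
      sse = object$local$sse_trace)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$update, y = .data$sse)) +
        ggplot2::geom_line() +
        ggplot2::labs(
          x = "single-edge update", y = "sum of squared differences",
          title = "Hill-climbing descent"
        )
    )
  }
  ggplot2::ggplot(
    object$ga$trace,
    ggplot2::aes(x = .data$generation, y = .data$best_fitness)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$fitness, linetype = "dashed") +
    ggplot2::labs(
      x = "generation", y = "best fitness",
      title = "Genetic-algorithm progress",
      subtitle = sprintf("dashed: fitness after local optimization (%.4f)", object$fitness)
    )
}

#' @rdname autoplot.signal_fit
#' @export
autoplot.ga_result <- function(object, ...) {
  ggplot2::ggplot(
    object$trace,
    ggplot2::aes(x = .data$generation, y = .data$best_fitness)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "best fitness",
      title = "Genetic-algorithm progress")
}

#' Histogram of fitted edge probabilities
#'
#' Displays how the fitted probabilities spread over `[0, 1]` using the
#' same ten bins as [probability_entropy()].
#'
#' @param fit A `signal_fit` object (or a bare probability vector).
#' @param bins Number of bins (default 10).
#' @return A ggplot object.
#' @export
plot_probability_spread <- function(fit, bins = 10) {
  values <- if (inherits(fit, "signal_fit")) fit$psi else as.numeric(fit)
  df <- tibble::tibble(probability = values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$probability)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, length.out = bins + 1),
      closed = "left", fill = "grey35") +
    ggplot2::labs(
      x = "edge probability", y = "count",
      title = "Spread of fitted interaction probabilities",
      subtitle = sprintf("bin entropy: %.3f", probability_entropy(values, bins))
    )
}
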