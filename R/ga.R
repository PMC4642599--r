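#' Fitness and gap of a candidate probability assignment
#'
#' Fitness of a candidate solution is
#' `F = 1 - ||C - R||_2 / |S x T|` with
#' `||C - R||_2 = sqrt(sum((C - R)^2))`: 1 means the computed reachability
#' matrix reproduces the empirical matrix exactly, and values fall in
#' `[0, 1]` because every squared entry difference is at most 1. The gap is
#' the signed sum `sum(C - R)`: positive when the assignment underestimates
#' reachability in aggregate, negative when it overestimates. [reach_quality()]
#' is the same quantity as fitness expressed as a percentage.
#'
#' @param C Empirical reachability matrix (sources x targets).
#' @param R Computed reachability matrix of the same shape.
#' @return A single number.
#' @examples
#' C <- matrix(c(0.5, 0.5), 1, 2)
#' R <- matrix(c(0.1, 0.8), 1, 2)
#' solution_fitness(C, R) # 1 - sqrt(0.16 + 0.09) / 2 = 0.75
#' solution_gap(C, R) # 0.1
#' @export
solution_fitness <- function(C, R) {
  check_conformable(C, R)
  1 - sqrt(sum((C - R)^2)) / length(C)
}

#' @rdname solution_fitness
#' @export
solution_gap <- function(C, R) {
  check_conformable(C, R)
  sum(C - R)
}

check_conformable <- function(C, R) {
  if (!is.numeric(C) || !is.numeric(R)) {
    stop("`C` and `R` must be numeric matrices", call. = FALSE)
  }
  if (!all(dim(as.matrix(C)) == dim(as.matrix(R)))) {
    stop("`C` and `R` must have identical dimensions", call. = FALSE)
  }
  invisible(TRUE)
}

#' Genetic-algorithm operators over edge-probability vectors
#'
#' The global phase of the fit is a genetic algorithm over vectors
#' `psi` of `|E|` edge probabilities. `ga_initialize()` draws a seed
#' population i.i.d. uniform on `[0, 1]` and scores it.
#' `ga_crossover()` combines two parents entrywise using their gap signs:
#' when both gaps are non-negative both parents likely underestimate, so the
#' larger entry is taken; when both are negative the smaller; with mixed
#' signs each entry comes from parent 1 with probability
#' `F1 / (F1 + F2)`. `ga_mutate()` replaces each entry with a fresh
#' uniform draw after an independent Bernoulli trial. `ga_select()` reduces
#' a doubled population back to its target size by keeping the `n_elite`
#' fittest plus fitness-proportional draws (without replacement) from the
#' rest.
#'
#' @param network A [signal_network()].
#' @param C Empirical reachability matrix (aligned to the network's declared
#'   sources and targets).
#' @param size Population size (default 50).
#' @param term_cap Passed to the reachability engine.
#' @return `ga_initialize()`: a list with matrix `psi` (`size` rows, one per
#'   candidate), numeric vectors `fitness` and `gap`, and `R` (list of
#'   cached reachability matrices).
#' @export
ga_initialize <- function(network, C, size = 50, term_cap = 2e6) {
  stopifnot(size >= 1, n_edges(network) >= 1)
  C <- align_matrix(C, network)
  psi <- matrix(stats::runif(size * n_edges(network)), nrow = size)
  scored <- score_population(network, C, psi, term_cap)
  list(psi = psi, fitness = scored$fitness, gap = scored$gap, R = scored$R)
}

score_population <- function(network, C, psi, term_cap = 2e6) {
  R <- lapply(seq_len(nrow(psi)), function(i) {
    reachability_matrix(network, probabilities = psi[i, ], term_cap = term_cap)
  })
  list(
    fitness = vapply(R, function(r) solution_fitness(C, r), numeric(1)),
    gap = vapply(R, function(r) solution_gap(C, r), numeric(1)),
    R = R
  )
}

#' @rdname ga_initialize
#' @param psi1,psi2 Parent probability vectors of equal length.
#' @param gap1,gap2 Their gap values; a gap of exactly 0 counts as positive.
#' @param fitness1,fitness2 Their fitness values (used for the mixed-sign
#'   proportional pick).
#' @export
ga_crossover <- function(psi1, psi2, gap1, gap2, fitness1, fitness2) {
  if (length(psi1) != length(psi2)) {
    stop("parent vectors must have equal length", call. = FALSE)
  }
  if (gap1 >= 0 && gap2 >= 0) {
    pmax(psi1, psi2)
  } else if (gap1 < 0 && gap2 < 0) {
    pmin(psi1, psi2)
  } else {
    w <- if (fitness1 + fitness2 > 0) fitness1 / (fitness1 + fitness2) else 0.5
    take1 <- stats::runif(length(psi1)) < w
    ifelse(take1, psi1, psi2)
  }
}

#' @rdname ga_initialize
#' @param psi A probability vector.
#' @param rate Per-entry mutation probability (default 0.01).
#' @export
ga_mutate <- function(psi, rate = 0.01) {
  stopifnot(rate >= 0, rate <= 1)
  hit <- stats::runif(length(psi)) < rate
  psi[hit] <- stats::runif(sum(hit))
  psi
}

#' @rdname ga_initialize
#' @param fitness Fitness vector of the doubled population.
#' @param n_keep Target population size after selection.
#' @param n_elite Number of top-fitness solutions kept unconditionally.
#' @return `ga_select()`: integer indices of the retained solutions.
#' @export
ga_select <- function(fitness, n_keep = 50, n_elite = 5) {
  n <- length(fitness)
  if (n != 2 * n_keep) {
    stop(sprintf("selection expects exactly %d solutions, got %d", 2 * n_keep, n),
      call. = FALSE
    )
  }
  ord <- order(fitness, decreasing = TRUE)
  elite <- ord[seq_len(n_elite)]
  rest <- setdiff(seq_len(n), elite)
  w <- fitness[rest]
  if (sum(w) <= 0) w <- rep(1, length(rest))
  drawn <- rest[sample.int(length(rest), n_keep - n_elite, replace = FALSE, prob = w)]
  c(elite, drawn)
}

# fitness-proportional draw of two distinct parent indices; independent
# proportional draws, redrawn on collision
pick_parents <- function(fitness) {
  w <- fitness
  if (sum(w) <= 0) w <- rep(1, length(fitness))
  repeat {
    pair <- c(
      sample.int(length(fitness), 1, prob = w),
      sample.int(length(fitness), 1, prob = w)
    )
    if (pair[1] != pair[2]) {
      return(pair)
    }
  }
}

#' Phase 1: global optimization by genetic algorithm
#'
#' Evolves a population of edge-probability vectors toward the empirical
#' reachability matrix `C`. Each generation draws `population_size`
#' crossover children (parents sampled fitness-proportionally), applies
#' mutation across the doubled population, and selects back to
#' `population_size` with elitism. The returned solution is the best ever
#' archived, whose fitness is non-decreasing across generations.
#'
#' @inheritParams ga_initialize
#' @param iterations Number of generations (the convergence point depends on
#'   the network and is a matter of trial and error; default 100).
#' @param population_size Population size after every selection (default 50).
#' @param mutation_rate Per-entry Bernoulli mutation probability
#'   (default 0.01).
#' @param n_elite Elite count in selection (default 5).
#' @param seed Optional integer seed; fixing it makes the run fully
#'   reproducible.
#' @return An object of class `ga_result`: list with `psi` (best-ever
#'   probability vector), `fitness`, `gap`, `R` (its reachability matrix)
#'   and `trace` (a tibble with one row per generation: `generation`,
#'   `best_fitness`, `mean_fitness`).
#' @export
run_ga <- function(network, C, iterations = 100, population_size = 50,
                   mutation_rate = 0.01, n_elite = 5, seed = NULL,
                   term_cap = 2e6) {
  stopifnot(iterations >= 1)
  C <- align_matrix(C, network)
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      run_ga(network, C, iterations, population_size, mutation_rate,
        n_elite,
        seed = NULL, term_cap = term_cap
      )
    ))
  }

  pop <- ga_initialize(network, C, size = population_size, term_cap = term_cap)
  best_i <- which.max(pop$fitness)
  best <- list(
    psi = pop$psi[best_i, ], fitness = pop$fitness[best_i],
    gap = pop$gap[best_i], R = pop$R[[best_i]]
  )
  trace <- vector("list", iterations)

  for (gen in seq_len(iterations)) {
    children <- matrix(0, nrow = population_size, ncol = n_edges(network))
    for (k in seq_len(population_size)) {
      pr <- pick_parents(pop$fitness)
      children[k, ] <- ga_crossover(
        pop$psi[pr[1], ], pop$psi[pr[2], ],
        pop$gap[pr[1]], pop$gap[pr[2]],
        pop$fitness[pr[1]], pop$fitness[pr[2]]
      )
    }
    psi <- rbind(pop$psi, children)
    # mutation over the full doubled population
    hit <- matrix(stats::runif(length(psi)) < mutation_rate, nrow = nrow(psi))
    psi[hit] <- stats::runif(sum(hit))

    # rescore what changed; originals untouched by mutation keep their cache
    changed <- c(apply(hit[seq_len(population_size), , drop = FALSE], 1, any),
      rep(TRUE, population_size))
    fitness <- c(pop$fitness, rep(NA_real_, population_size))
    gap <- c(pop$gap, rep(NA_real_, population_size))
    R <- c(pop$R, vector("list", population_size))
    for (i in which(changed)) {
      R[[i]] <- reachability_matrix(network, probabilities = psi[i, ], term_cap = term_cap)
      fitness[i] <- solution_fitness(C, R[[i]])
      gap[i] <- solution_gap(C, R[[i]])
    }

    keep <- ga_select(fitness, n_keep = population_size, n_elite = n_elite)
    pop <- list(
      psi = psi[keep, , drop = FALSE], fitness = fitness[keep],
      gap = gap[keep], R = R[keep]
    )

    gen_best <- which.max(pop$fitness)
    if (pop$fitness[gen_best] > best$fitness) {
      best <- list(
        psi = pop$psi[gen_best, ], fitness = pop$fitness[gen_best],
        gap = pop$gap[gen_best], R = pop$R[[gen_best]]
      )
    }
    trace[[gen]] <- tibble::tibble(
      generation = gen,
      best_fitness = best$fitness,
      mean_fitness = mean(pop$fitness),
      population = nrow(pop$psi)
    )
  }

  structure(
    list(
      psi = best$psi, fitness = best$fitness, gap = best$gap, R = best$R,
      trace = dplyr::bind_rows(trace)
    ),
    class = "ga_result"
  )
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "<ga_result> %d edges, best fitness %.6f (gap %+.4f) after %d generation(s)\n",
    length(x$psi), x$fitness, x$gap, nrow(x$trace)
  ))
  invisible(x)
}
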