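#' Result quality as a percentage
#'
#' `100 * (1 - sqrt(sum((C - R)^2)) / (|S| * |T|))` — the fitness of
#' [solution_fitness()] on a percentage scale. The closer to 100, the
#' closer the computed reachability matrix is to the empirical one.
#'
#' @inheritParams solution_fitness
#' @return A percentage in `[0, 100]`.
#' @export
reach_quality <- function(C, R) 100 * solution_fitness(C, R)

#' Entropy of the probability spread over [0, 1]
#'
#' Divides `[0, 1]` into `bins` equal-width intervals (half-open, with the
#' final bin closed at 1), counts the values per bin, and returns the
#' natural-log entropy `-sum(p(b) * log(p(b)))` of the bin frequencies,
#' with `0 * log(0) = 0`. Higher entropy means the probabilities are more
#' spread across the spectrum; 0 means they crowd a single bin, and the
#' maximum `log(bins)` is reached only by a uniform histogram.
#'
#' @param values Numeric vector of probabilities in `[0, 1]`.
#' @param bins Number of bins (default 10).
#' @return Entropy in nats, in `[0, log(bins)]`.
#' @examples
#' probability_entropy(seq(0.05, 0.95, by = 0.1)) # log(10)
#' @export
probability_entropy <- function(values, bins = 10) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("`values` must be non-empty", call. = FALSE)
  if (any(is.na(values)) || any(values < 0 | values > 1)) {
    stop("`values` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(bins >= 2)
  idx <- pmin(floor(values * bins) + 1, bins) # last bin closed at 1
  p <- tabulate(idx, nbins = bins) / length(values)
  p <- p[p > 0]
  -sum(p * log(p))
}

# accept condition profiles as a wide data frame (one row per condition,
# a `condition` column plus one numeric column per edge) or a named list /
# matrix of probability vectors; returns a conditions x edges matrix
profile_matrix <- function(profiles) {
  if (is.data.frame(profiles)) {
    if (!"condition" %in% names(profiles)) {
      stop("`profiles` data frame needs a `condition` column", call. = FALSE)
    }
    cond <- as.character(profiles$condition)
    mat <- as.matrix(profiles[, setdiff(names(profiles), "condition"), drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- cond
  } else if (is.matrix(profiles)) {
    mat <- profiles
    if (is.null(rownames(mat))) {
      rownames(mat) <- sprintf("condition%d", seq_len(nrow(mat)))
    }
  } else if (is.list(profiles)) {
    lens <- lengths(profiles)
    if (length(unique(lens)) != 1) {
      stop("all condition profiles must have the same number of edges", call. = FALSE)
    }
    mat <- do.call(rbind, profiles)
    if (is.null(rownames(mat))) {
      rownames(mat) <- names(profiles) %||% sprintf("condition%d", seq_along(profiles))
    }
  } else {
    stop("`profiles` must be a data frame, matrix, or list of vectors", call. = FALSE)
  }
  if (anyNA(mat)) stop("profiles contain missing values", call. = FALSE)
  mat
}

#' Pairwise distances between condition profiles
#'
#' Represents each condition (e.g. a disease subtype) by its vector of
#' fitted edge probabilities — all conditions sharing one edge ordering —
#' and computes the Euclidean distance between every pair of conditions,
#' plus, for each condition, the average distance to all others. Large
#' average distances indicate a condition whose signaling profile stands
#' apart.
#'
#' @param profiles Condition profiles: a wide data frame with a `condition`
#'   column and one numeric column per edge, a conditions-by-edges matrix
#'   with row names, or a named list of equal-length probability vectors.
#' @return An object of class `condition_distances`: list with `distances`
#'   (symmetric matrix) and `mean_distance` (tibble: `condition`,
#'   `mean_distance`). [tidy()] returns the pairwise distances long.
#' @export
condition_distances <- function(profiles) {
  mat <- profile_matrix(profiles)
  if (nrow(mat) < 2) stop("need at least 2 conditions", call. = FALSE)
  d <- as.matrix(stats::dist(mat, method = "euclidean"))
  mean_d <- rowSums(d) / (nrow(d) - 1)
  structure(
    list(
      distances = d,
      mean_distance = tibble::tibble(
        condition = rownames(d),
        mean_distance = unname(mean_d)
      )
    ),
    class = "condition_distances"
  )
}

#' @export
print.condition_distances <- function(x, ...) {
  cat(sprintf("<condition_distances> %d conditions\n", nrow(x$distances)))
  print(x$mean_distance, ...)
  invisible(x)
}

#' @export
tidy.condition_distances <- function(x, ...) {
  d <- x$distances
  idx <- which(upper.tri(d), arr.ind = TRUE)
  tibble::tibble(
    condition1 = rownames(d)[idx[, 1]],
    condition2 = colnames(d)[idx[, 2]],
    distance = d[idx]
  )
}

#' @export
autoplot.condition_distances <- function(object, ...) {
  d <- object$distances
  df <- tidyr::expand_grid(
    condition1 = rownames(d),
    condition2 = colnames(d)
  )
  df$distance <- as.vector(t(d))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$condition2, y = .data$condition1, fill = .data$distance
  )) +
    ggplot2::geom_tile() +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "distance",
      title = "Euclidean distances between condition profiles"
    )
}

#' Outstanding interactions and genes across conditions
#'
#' For every edge, computes the mean and (population) standard deviation of
#' its fitted probability across all conditions, then flags every
#' (condition, edge) pair whose probability lies at least
#' `threshold * sigma` away from the mean. The outstanding gene set `L` of
#' a condition is the union of the endpoint genes of its flagged edges —
#' the input for downstream enrichment analysis. Edges whose probabilities
#' are identical across conditions have `sigma = 0` and are never flagged.
#'
#' @param profiles Condition profiles (see [condition_distances()] for the
#'   accepted shapes); at least 3 conditions.
#' @param network The shared [signal_network()]; profile columns must follow
#'   its edge order.
#' @param threshold Flagging threshold in standard deviations (default 2).
#' @return An object of class `outstanding_report`: list with `edge_stats`
#'   (tibble: `edge`, `from`, `to`, `mu`, `sigma`), `flagged` (tibble:
#'   `condition`, `edge`, `from`, `to`, `probability`, `deviation`), and
#'   `genes` (tibble: `condition`, `gene` — the sets `L`). [tidy()] returns
#'   the flagged pairs.
#' @export
outstanding_interactions <- function(profiles, network, threshold = 2) {
  stopifnot(inherits(network, "signal_network"))
  mat <- profile_matrix(profiles)
  if (nrow(mat) < 3) {
    stop("need at least 3 conditions for a meaningful standard deviation",
      call. = FALSE
    )
  }
  if (ncol(mat) != n_edges(network)) {
    stop(sprintf(
      "profiles have %d columns but the network has %d edges",
      ncol(mat), n_edges(network)
    ), call. = FALSE)
  }
  mu <- colMeans(mat)
  sigma <- sqrt(colMeans(sweep(mat, 2, mu)^2)) # population sd
  edge_stats <- tibble::tibble(
    edge = seq_len(ncol(mat)),
    from = network$edges$from,
    to = network$edges$to,
    mu = unname(mu),
    sigma = unname(sigma)
  )
  dev <- abs(sweep(mat, 2, mu))
  lim <- threshold * sigma
  hit <- which(sigma > 0 & t(dev) >= lim, arr.ind = TRUE) # edge x condition
  flagged <- tibble::tibble(
    condition = rownames(mat)[hit[, 2]],
    edge = as.integer(hit[, 1]),
    from = network$edges$from[hit[, 1]],
    to = network$edges$to[hit[, 1]],
    probability = mat[cbind(hit[, 2], hit[, 1])],
    deviation = dev[cbind(hit[, 2], hit[, 1])]
  )
  flagged <- dplyr::arrange(flagged, .data$condition, .data$edge)
  genes <- flagged |>
    tidyr::pivot_longer(c("from", "to"), values_to = "gene") |>
    dplyr::distinct(.data$condition, .data$gene) |>
    dplyr::arrange(.data$condition, .data$gene)
  structure(
    list(edge_stats = edge_stats, flagged = flagged, genes = genes,
      threshold = threshold),
    class = "outstanding_report"
  )
}

#' @export
print.outstanding_report <- function(x, ...) {
  cat(sprintf(
    "<outstanding_report> %d flagged (condition, edge) pair(s) at %.3g sd\n",
    nrow(x$flagged), x$threshold
  ))
  if (nrow(x$flagged) > 0) print(x$flagged, ...)
  invisible(x)
}

#' @export
tidy.outstanding_report <- function(x, ...) x$flagged

#' @export
autoplot.outstanding_report <- function(object, ...) {
  stats <- object$edge_stats
  band <- tibble::tibble(
    edge = stats$edge,
    lo = pmax(0, stats$mu - object$threshold * stats$sigma),
    hi = pmin(1, stats$mu + object$threshold * stats$sigma)
  )
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$edge, ymin = .data$lo, ymax = .data$hi),
      fill = "grey85"
    ) +
    ggplot2::geom_line(
      data = stats,
      ggplot2::aes(x = .data$edge, y = .data$mu), color = "grey40"
    ) +
    ggplot2::geom_point(
      data = object$flagged,
      ggplot2::aes(x = .data$edge, y = .data$probability,
        color = .data$condition)
    ) +
    ggplot2::labs(
      x = "edge index", y = "probability",
      title = "Outstanding interactions",
      subtitle = sprintf(
        "band: mean +/- %.3g population sd across conditions", object$threshold
      )
    )
}

#' Removal-based node centrality
#'
#' Scores each gene by its contribution to signal reachability: the total
#' drop in the source-to-target reachability matrix when every edge
#' incident to the gene is removed,
#' `centrality(v) = sum over (s, t) of R[s, t] - R_without_v[s, t]`,
#' where pairs having `v` itself as source or target are excluded. By
#' monotonicity of reachability in the edge set, centrality is
#' non-negative, and it is exactly 0 for nodes off every source-target
#' path. Reported as "removal centrality" — one direct operationalization
#' of reachability contribution.
#'
#' @param network A [signal_network()] with declared sources and targets.
#' @param probabilities Optional probability vector (defaults to the
#'   network's own).
#' @param term_cap Passed to the reachability engine.
#' @return A tibble with columns `node` and `centrality`, in node order.
#' @export
node_centrality <- function(network, probabilities = NULL, term_cap = 2e6) {
  stopifnot(inherits(network, "signal_network"))
  probabilities <- resolve_probabilities(network, probabilities)
  R <- reachability_matrix(network, probabilities = probabilities, term_cap = term_cap)
  centrality <- vapply(network$nodes, function(v) {
    keep <- network$edges$from != v & network$edges$to != v
    sub <- network
    sub$edges <- network$edges[keep, , drop = FALSE]
    R_wo <- reachability_matrix(sub,
      probabilities = probabilities[keep],
      term_cap = term_cap
    )
    ok_s <- network$sources != v
    ok_t <- network$targets != v
    sum(R[ok_s, ok_t, drop = FALSE] - R_wo[ok_s, ok_t, drop = FALSE])
  }, numeric(1))
  tibble::tibble(node = network$nodes, centrality = unname(centrality))
}
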