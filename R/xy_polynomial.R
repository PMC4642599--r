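#' xy-polynomial mechanics for exact signal reachability
#'
#' The exact reachability computation represents the joint state of the
#' edges processed so far as an *xy-polynomial*: a collection of terms, each
#' fixing a subset of the processed edges as present (the `x` variables) and
#' the complement as absent (the `y` variables), with a coefficient equal to
#' the probability of that joint outcome, plus two free coefficients --
#' `b`, the probability mass already known to reach the target (`x*`), and
#' `c`, the mass already known to be cut off (`y*`). Multiplying in one edge
#' binomial `p x_e + (1 - p) y_e` splits every term in two; collapsing then
#' moves any term whose present edges contain a source->target path into
#' `b`, and any term whose absent edges already disconnect source from
#' target into `c`. Total probability `b + c + sum(a_i)` is conserved at 1
#' throughout.
#'
#' These functions expose the mechanics step by step on a plain list
#' structure. [reachability()] runs the same algorithm in compiled code;
#' the two agree to machine precision (and with subset enumeration) on any
#' network.
#'
#' @param n_edges Number of edges of the network the polynomial ranges over.
#' @return `xy_polynomial()` returns an object of class `xy_polynomial`:
#'   a list with fields `n_edges`, `processed` (integer vector of edge
#'   indices already multiplied in), `terms` (named list mapping a
#'   `"|"`-prefixed comma-separated sorted present-edge subset to its
#'   coefficient; the key `"|"` alone is the empty subset), `b` and `c`.
#' @examples
#' poly <- xy_polynomial(2)
#' poly <- multiply_edge(poly, 1, 0.7)
#' poly$terms # present {1} with 0.7, empty subset with 0.3
#' @export
xy_polynomial <- function(n_edges) {
  stopifnot(n_edges >= 0)
  structure(
    list(
      n_edges = as.integer(n_edges),
      processed = integer(0),
      terms = stats::setNames(list(1), term_key(integer(0))),
      b = 0,
      c = 0
    ),
    class = "xy_polynomial"
  )
}

# keys are "|"-prefixed so the empty subset has a non-empty name (R lists
# cannot be indexed by the empty string)
term_key <- function(present) paste0("|", paste(sort(present), collapse = ","))
key_edges <- function(key) {
  body <- substring(key, 2)
  if (identical(body, "")) integer(0) else as.integer(strsplit(body, ",")[[1]])
}

#' @rdname xy_polynomial
#' @param poly An `xy_polynomial`.
#' @param edge Edge index to multiply in; must not have been processed yet.
#' @param p Existence probability of that edge.
#' @export
multiply_edge <- function(poly, edge, p) {
  stopifnot(inherits(poly, "xy_polynomial"))
  edge <- as.integer(edge)
  if (edge < 1 || edge > poly$n_edges) {
    stop(sprintf("edge index %d outside 1..%d", edge, poly$n_edges), call. = FALSE)
  }
  if (edge %in% poly$processed) {
    stop(sprintf("edge %d has already been multiplied into the polynomial", edge),
      call. = FALSE
    )
  }
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  new_terms <- list()
  for (key in names(poly$terms)) {
    a <- poly$terms[[key]]
    present <- key_edges(key)
    absent_coef <- a * (1 - p)
    present_coef <- a * p
    if (absent_coef > 0) new_terms[[term_key(present)]] <- absent_coef
    if (present_coef > 0) new_terms[[term_key(c(present, edge))]] <- present_coef
  }
  # free coefficients absorb both outcomes: b*p + b*(1-p) = b, likewise c
  poly$terms <- new_terms
  poly$processed <- c(poly$processed, edge)
  poly
}

#' @rdname xy_polynomial
#' @param network A [signal_network()] the polynomial's edge indices refer to.
#' @param source,target Node identifiers for the pair under evaluation.
#' @export
collapse_terms <- function(poly, network, source, target) {
  stopifnot(inherits(poly, "xy_polynomial"), inherits(network, "signal_network"))
  stopifnot(poly$n_edges == n_edges(network))
  s <- node_index(network, source)
  t <- node_index(network, target)
  ef <- match(network$edges$from, network$nodes)
  et <- match(network$edges$to, network$nodes)
  all_edges <- seq_len(poly$n_edges)
  keep <- list()
  for (key in names(poly$terms)) {
    a <- poly$terms[[key]]
    present <- key_edges(key)
    absent <- setdiff(poly$processed, present)
    if (edge_subset_reaches(ef, et, length(network$nodes), present, s, t)) {
      poly$b <- poly$b + a
    } else if (!edge_subset_reaches(
      ef, et, length(network$nodes), setdiff(all_edges, absent), s, t
    )) {
      poly$c <- poly$c + a
    } else {
      keep[[key]] <- a
    }
  }
  poly$terms <- keep
  poly
}

# directed path existence from s to t using only the listed edges (indices
# into ef/et); s == t counts as reached by the empty path
edge_subset_reaches <- function(ef, et, n_nodes, edges, s, t) {
  if (s == t) {
    return(TRUE)
  }
  if (length(edges) == 0) {
    return(FALSE)
  }
  ef <- ef[edges]
  et <- et[edges]
  seen <- logical(n_nodes)
  seen[s] <- TRUE
  frontier <- s
  while (length(frontier) > 0) {
    hit <- ef %in% frontier
    nxt <- unique(et[hit][!seen[et[hit]]])
    if (t %in% nxt) {
      return(TRUE)
    }
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

# conservation diagnostic: b + c + sum of term coefficients
poly_mass <- function(poly) poly$b + poly$c + sum(unlist(poly$terms))

# reference implementation of pair reachability built from the stepwise
# mechanics above; used as a cross-check for the compiled engine
reachability_stepwise <- function(network, probabilities, source, target,
                                  order = NULL) {
  probabilities <- resolve_probabilities(network, probabilities)
  if (source == target) {
    node_index(network, source)
    return(1)
  }
  node_index(network, c(source, target))
  poly <- xy_polynomial(n_edges(network))
  order <- order %||% seq_len(n_edges(network))
  poly <- collapse_terms(poly, network, source, target)
  if (poly$b == 1) {
    return(1)
  }
  if (poly$c == 1) {
    return(0)
  }
  for (e in order) {
    poly <- multiply_edge(poly, e, probabilities[e])
    poly <- collapse_terms(poly, network, source, target)
    if (abs(poly_mass(poly) - 1) > 1e-9) {
      stop("xy-polynomial conservation drifted beyond 1e-9", call. = FALSE)
    }
  }
  poly$b
}
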