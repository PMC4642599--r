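#' Construct a probabilistic signaling network
#'
#' A signaling network is a directed graph whose nodes are genes and whose
#' edges are interactions, each optionally carrying an existence probability
#' in `[0, 1]`. A subset of nodes is designated as sources (membrane
#' receptors) and another as targets (reporters, i.e. transcription factors);
#' signal reachability is always computed from a source to a target. Edge
#' identity is positional: edge `i` is row `i` of the edge table, and every
#' probability vector used elsewhere in the package follows that order.
#'
#' @param edges A data frame whose first two columns are the source and
#'   target node of each directed edge (columns named `from`/`to` are used by
#'   name when present). An optional third column (or a column named
#'   `probability`) gives the edge probability.
#' @param sources,targets Character vectors of source and target node
#'   identifiers. May be empty at construction time, but must be non-empty
#'   (and disjoint from each other is not required) before a reachability
#'   matrix is requested.
#' @param nodes Optional character vector of node identifiers; defaults to
#'   the nodes referenced by `edges`, `sources` and `targets`. Extra isolated
#'   nodes may be declared here.
#' @param allow_parallel Allow two edges with identical endpoints. The
#'   interaction model has one probability per interaction, so parallel
#'   edges are rejected by default; the flag exists for textbook topologies
#'   such as the two-parallel-edge fixture.
#' @return An object of class `signal_network`: a list with elements
#'   `edges` (a tibble with columns `from`, `to`, `probability`), `nodes`,
#'   `sources` and `targets`.
#' @examples
#' net <- signal_network(
#'   data.frame(from = c("A", "A", "B"), to = c("B", "C", "C")),
#'   sources = "A", targets = "C"
#' )
#' net
#' @export
signal_network <- function(edges, sources = character(), targets = character(),
                           nodes = NULL, allow_parallel = FALSE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) {
    stop("`edges` needs at least two columns (from, to)", call. = FALSE)
  }
  from_col <- if ("from" %in% names(edges)) "from" else names(edges)[1]
  to_col <- if ("to" %in% names(edges)) "to" else names(edges)[2]
  prob_col <- if ("probability" %in% names(edges)) {
    "probability"
  } else if (ncol(edges) >= 3) {
    names(edges)[3]
  } else {
    NULL
  }
  from <- as.character(edges[[from_col]])
  to <- as.character(edges[[to_col]])
  prob <- if (is.null(prob_col)) rep(NA_real_, length(from)) else as.numeric(edges[[prob_col]])

  loops <- from == to
  if (any(loops)) {
    warning(sprintf(
      "dropped %d self-loop edge(s) (%s): a self-loop cannot affect source->target reachability",
      sum(loops), paste(unique(from[loops]), collapse = ", ")
    ), call. = FALSE)
    from <- from[!loops]
    to <- to[!loops]
    prob <- prob[!loops]
  }

  key <- paste(from, to, sep = "\r")
  if (!allow_parallel && anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    dup <- gsub("\r", " -> ", dup, fixed = TRUE)
    stop(sprintf("duplicate directed edge(s): %s", paste(dup, collapse = ", ")),
      call. = FALSE
    )
  }
  if (any(!is.na(prob) & (prob < 0 | prob > 1))) {
    bad <- which(!is.na(prob) & (prob < 0 | prob > 1))
    stop(sprintf(
      "edge probabilities must lie in [0, 1]; offending edge index(es): %s",
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }

  sources <- as.character(sources)
  targets <- as.character(targets)
  all_nodes <- unique(c(from, to, sources, targets, as.character(nodes %||% character())))
  if (!is.null(nodes)) {
    missing <- setdiff(c(from, to, sources, targets), as.character(nodes))
    if (length(missing) > 0) {
      stop(sprintf(
        "node(s) referenced but not declared in `nodes`: %s",
        paste(unique(missing), collapse = ", ")
      ), call. = FALSE)
    }
    all_nodes <- as.character(nodes)
  }

  structure(
    list(
      edges = tibble::tibble(from = from, to = to, probability = prob),
      nodes = all_nodes,
      sources = sources,
      targets = targets
    ),
    class = "signal_network"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.signal_network <- function(x, ...) {
  n_p <- sum(!is.na(x$edges$probability))
  cat(sprintf(
    "<signal_network> %d nodes, %d directed edges (%s), %d source(s), %d target(s)\n",
    length(x$nodes), nrow(x$edges),
    if (n_p == nrow(x$edges)) "probabilities set" else sprintf("%d probabilities set", n_p),
    length(x$sources), length(x$targets)
  ))
  print(x$edges, ...)
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @export
as_tibble.signal_network <- function(x, ...) x$edges

#' Number of edges / nodes of a network
#' @param network A [signal_network()].
#' @return An integer count.
#' @export
n_edges <- function(network) nrow(network$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(network) length(network$nodes)

#' Get or set the edge probability vector
#'
#' @param network A [signal_network()].
#' @param probabilities Numeric vector of length `n_edges(network)` with
#'   entries in `[0, 1]`, in edge (row) order.
#' @return `edge_probabilities()` returns the probability vector (possibly
#'   containing `NA` where unset); `set_probabilities()` returns the network
#'   with its probability column replaced.
#' @export
edge_probabilities <- function(network) {
  stopifnot(inherits(network, "signal_network"))
  network$edges$probability
}

#' @rdname edge_probabilities
#' @export
set_probabilities <- function(network, probabilities) {
  stopifnot(inherits(network, "signal_network"))
  probabilities <- as.numeric(probabilities)
  if (length(probabilities) != n_edges(network)) {
    stop(sprintf(
      "`probabilities` must have one entry per edge (%d), got %d",
      n_edges(network), length(probabilities)
    ), call. = FALSE)
  }
  if (any(is.na(probabilities)) || any(probabilities < 0 | probabilities > 1)) {
    stop("`probabilities` must all lie in [0, 1]", call. = FALSE)
  }
  network$edges$probability <- probabilities
  network
}

# resolve a probability vector for computation: explicit argument wins,
# otherwise the network's own column, which must then be fully set
resolve_probabilities <- function(network, probabilities) {
  if (is.null(probabilities)) {
    probabilities <- network$edges$probability
    if (anyNA(probabilities)) {
      stop("network has unset edge probabilities; supply `probabilities`",
        call. = FALSE
      )
    }
  }
  probabilities <- as.numeric(probabilities)
  if (length(probabilities) != n_edges(network)) {
    stop(sprintf(
      "probability vector length %d does not match edge count %d",
      length(probabilities), n_edges(network)
    ), call. = FALSE)
  }
  if (any(is.na(probabilities)) || any(probabilities < 0 | probabilities > 1)) {
    stop("edge probabilities must lie in [0, 1]", call. = FALSE)
  }
  probabilities
}

node_index <- function(network, node) {
  i <- match(node, network$nodes)
  if (anyNA(i)) {
    stop(sprintf(
      "unknown node(s): %s", paste(node[is.na(i)], collapse = ", ")
    ), call. = FALSE)
  }
  i
}

#' Read a directed network from a delimited edge-list file
#'
#' Each non-comment line holds two or three whitespace- or tab-delimited
#' fields: `source target [probability]`. Lines starting with `#` and blank
#' lines are skipped. Edge order in the returned network is file order.
#' Self-loops are dropped with a warning (they cannot affect source->target
#' reachability); duplicate directed edges and probabilities outside
#' `[0, 1]` are errors.
#'
#' @param path Path to the edge-list file.
#' @param sources,targets Optional character vectors of source/target nodes.
#' @param sif Treat lines as three-column SIF (`source relation target`):
#'   the middle token is ignored and no probabilities are read.
#' @return A [signal_network()].
#' @export
read_network <- function(path, sources = character(), targets = character(),
                         sif = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  from <- character(0)
  to <- character(0)
  prob <- numeric(0)
  for (k in idx) {
    fields <- strsplit(trimws(lines[[k]]), "[ \t]+")[[1]]
    if (sif) {
      if (length(fields) != 3) {
        stop(sprintf("line %d: SIF lines need exactly 3 fields, got %d", k, length(fields)),
          call. = FALSE
        )
      }
      from <- c(from, fields[1])
      to <- c(to, fields[3])
      prob <- c(prob, NA_real_)
      next
    }
    if (!length(fields) %in% c(2L, 3L)) {
      stop(sprintf("line %d: expected 2 or 3 fields, got %d", k, length(fields)),
        call. = FALSE
      )
    }
    p <- NA_real_
    if (length(fields) == 3L) {
      p <- suppressWarnings(as.numeric(fields[3]))
      if (is.na(p)) {
        stop(sprintf("line %d: cannot parse probability '%s'", k, fields[3]),
          call. = FALSE
        )
      }
      if (p < 0 || p > 1) {
        stop(sprintf("line %d: probability %s outside [0, 1]", k, fields[3]),
          call. = FALSE
        )
      }
    }
    from <- c(from, fields[1])
    to <- c(to, fields[2])
    prob <- c(prob, p)
  }
  signal_network(
    data.frame(from = from, to = to, probability = prob, stringsAsFactors = FALSE),
    sources = sources, targets = targets
  )
}

#' Write fitted edge probabilities as a three-column edge list
#'
#' Writes `from<TAB>to<TAB>probability` in edge order with six decimal
#' digits, a format that round-trips through [read_network()].
#'
#' @param network A [signal_network()] with all probabilities set.
#' @param path Output file path.
#' @param digits Decimal digits used for serialization.
#' @return Invisibly, `path`.
#' @export
write_probabilities <- function(network, path, digits = 6) {
  stopifnot(inherits(network, "signal_network"))
  p <- network$edges$probability
  if (nrow(network$edges) > 0 && anyNA(p)) {
    stop("network has unset edge probabilities; nothing to write", call. = FALSE)
  }
  lines <- if (nrow(network$edges) == 0) {
    character(0)
  } else {
    sprintf(
      "%s\t%s\t%s", network$edges$from, network$edges$to,
      formatC(p, format = "f", digits = digits)
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a labeled reachability matrix
#'
#' The on-disk format is a tab-delimited table whose first row holds the
#' target labels and whose first column holds the source labels; every entry
#' must parse as a real number in `[0, 1]`. This is the format of both the
#' empirical matrix `C` and a computed reachability matrix.
#'
#' @param path File path.
#' @return `read_matrix()` returns a numeric matrix with source row names
#'   and target column names.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2) stop("matrix file needs a header row and at least one data row", call. = FALSE)
  split <- lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1]])
  targets <- split[[1]]
  # tolerate an optional corner label in the header
  body <- split[-1]
  widths <- vapply(body, length, integer(1))
  if (length(unique(widths)) != 1) {
    stop("ragged rows: matrix rows have differing field counts", call. = FALSE)
  }
  if (widths[1] == length(targets) + 1) {
    # header had no corner label
  } else if (widths[1] == length(targets)) {
    targets <- targets[-1]
  } else {
    stop("header and row widths are inconsistent", call. = FALSE)
  }
  sources <- vapply(body, `[`, character(1), 1)
  vals <- t(vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop("non-numeric matrix entry", call. = FALSE)
    v
  }, numeric(length(targets))))
  if (length(targets) == 1) vals <- matrix(vals, ncol = 1)
  if (any(vals < 0 | vals > 1)) {
    stop("matrix entries must lie in [0, 1]", call. = FALSE)
  }
  dimnames(vals) <- list(sources, targets)
  vals
}

#' @rdname read_matrix
#' @param x A numeric matrix with row (source) and column (target) names.
#' @param digits Decimal digits used for serialization.
#' @export
write_matrix <- function(x, path, digits = 6) {
  stopifnot(is.matrix(x))
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("matrix must have source row names and target column names", call. = FALSE)
  }
  header <- paste(c(".", colnames(x)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], formatC(x[i, ], format = "f", digits = digits)),
      collapse = "\t"
    )
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a one-node-per-line list (e.g. source or target genes)
#' @param path File path; blank lines and `#` comments are skipped.
#' @return Character vector of node identifiers.
#' @export
read_node_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- trimws(readLines(path))
  lines[!grepl("^(#|$)", lines)]
}

# check an |S| x |T| matrix against a network's declared sources/targets and
# return it with rows/columns aligned to the network's ordering
align_matrix <- function(C, network) {
  if (!is.matrix(C)) C <- as.matrix(C)
  if (!is.numeric(C)) stop("`C` must be a numeric matrix", call. = FALSE)
  src <- network$sources
  tgt <- network$targets
  if (length(src) == 0 || length(tgt) == 0) {
    stop("network must declare non-empty source and target sets", call. = FALSE)
  }
  if (!is.null(rownames(C)) && !is.null(colnames(C)) &&
    setequal(rownames(C), src) && setequal(colnames(C), tgt)) {
    C <- C[src, tgt, drop = FALSE]
  } else if (nrow(C) != length(src) || ncol(C) != length(tgt)) {
    stop(sprintf(
      "matrix is %dx%d but the network declares %d source(s) and %d target(s)",
      nrow(C), ncol(C), length(src), length(tgt)
    ), call. = FALSE)
  }
  if (any(C < 0 | C > 1)) stop("matrix entries must lie in [0, 1]", call. = FALSE)
  dimnames(C) <- list(src, tgt)
  C
}
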