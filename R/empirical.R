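#' Empirical reachability from gene coexpression
#'
#' The observed proxy for signal reachability between a receptor (source)
#' gene and a reporter (target) gene is the absolute value of the Pearson
#' correlation between their expression profiles across samples:
#' `C[s, t] = |cor(expr[s, ], expr[t, ])|`. Strong coexpression in either
#' direction is read as evidence that signal flows between the pair, so the
#' sign is discarded and every entry lies in `[0, 1]`.
#'
#' Expression rows with missing values are rejected outright (no silent
#' pairwise-complete correlation), and a gene with zero variance across the
#' samples has no defined correlation and is reported as an error. When
#' conditions (e.g. disease subtypes) are analyzed separately, subset the
#' columns to one condition's samples before calling this function: one fit
#' corresponds to one condition's expression.
#'
#' @param expr Expression data: a numeric matrix with gene row names, or a
#'   data frame whose first column holds gene identifiers and whose
#'   remaining columns are per-sample measurements.
#' @param sources,targets Character vectors of source and target gene
#'   identifiers; all must be present in `expr`.
#' @return A numeric matrix (`length(sources)` x `length(targets)`) of
#'   absolute Pearson correlations, with source row names and target column
#'   names.
#' @examples
#' expr <- matrix(rnorm(30), nrow = 3,
#'   dimnames = list(c("R1", "G2", "TF1"), NULL))
#' coexpression_matrix(expr, sources = "R1", targets = "TF1")
#' @export
coexpression_matrix <- function(expr, sources, targets) {
  expr <- as_expression_matrix(expr)
  sources <- as.character(sources)
  targets <- as.character(targets)
  if (length(sources) == 0 || length(targets) == 0) {
    stop("`sources` and `targets` must be non-empty", call. = FALSE)
  }
  missing <- setdiff(c(sources, targets), rownames(expr))
  if (length(missing) > 0) {
    stop(sprintf(
      "gene(s) absent from the expression data: %s",
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  if (ncol(expr) < 3) {
    stop("at least 3 samples are required to compute correlations", call. = FALSE)
  }
  used <- unique(c(sources, targets))
  sds <- apply(expr[used, , drop = FALSE], 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf(
      "zero-variance gene(s), correlation undefined: %s",
      paste(used[sds == 0], collapse = ", ")
    ), call. = FALSE)
  }
  C <- abs(stats::cor(
    t(expr[sources, , drop = FALSE]),
    t(expr[targets, , drop = FALSE])
  ))
  # guard against |r| creeping past 1 by floating-point round-off
  C[C > 1] <- 1
  dimnames(C) <- list(sources, targets)
  C
}

as_expression_matrix <- function(expr) {
  if (is.data.frame(expr)) {
    genes <- as.character(expr[[1]])
    mat <- as.matrix(expr[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- genes
    expr <- mat
  }
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("`expr` must be a numeric matrix or a gene-column data frame", call. = FALSE)
  }
  if (is.null(rownames(expr))) {
    stop("`expr` must carry gene identifiers as row names (or a first column)",
      call. = FALSE
    )
  }
  if (anyNA(expr)) {
    bad <- rownames(expr)[apply(expr, 1, anyNA)]
    stop(sprintf(
      "missing values in expression rows: %s (impute or drop them upstream)",
      paste(utils::head(bad, 10), collapse = ", ")
    ), call. = FALSE)
  }
  expr
}

#' Read an expression table
#'
#' Expects a tab- or whitespace-delimited table whose first row holds
#' sample labels and whose first column holds gene identifiers. An optional
#' two-column mapping file translates the table's identifiers (e.g. probe
#' ids) to network node names before they are matched.
#'
#' @param path Path to the expression table.
#' @param mapping Optional path to a two-column (from, to) identifier
#'   mapping file.
#' @return A numeric matrix with gene row names and sample column names.
#' @export
read_expression <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2) {
    stop("expression file needs a sample-label header and at least one gene row",
      call. = FALSE
    )
  }
  split <- lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1]])
  samples <- split[[1]]
  body <- split[-1]
  widths <- vapply(body, length, integer(1))
  if (length(unique(widths)) != 1) {
    stop("ragged rows in the expression table", call. = FALSE)
  }
  if (widths[1] == length(samples)) {
    samples <- samples[-1] # header carried a corner label
  } else if (widths[1] != length(samples) + 1) {
    stop("header and row widths are inconsistent", call. = FALSE)
  }
  genes <- vapply(body, `[`, character(1), 1)
  mat <- t(vapply(body, function(f) {
    suppressWarnings(as.numeric(f[-1]))
  }, numeric(length(samples))))
  if (length(samples) == 1) mat <- matrix(mat, ncol = 1)
  dimnames(mat) <- list(genes, samples)
  if (!is.null(mapping)) {
    map <- utils::read.table(mapping,
      header = FALSE, stringsAsFactors = FALSE,
      col.names = c("from", "to")
    )
    hit <- match(rownames(mat), map$from)
    rownames(mat)[!is.na(hit)] <- map$to[hit[!is.na(hit)]]
  }
  as_expression_matrix(mat)
}
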