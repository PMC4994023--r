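#' Construct a feature matrix
#'
#' A feature matrix holds molecular features (gene expression, copy number,
#' binary mutation status, ...) for a panel of cell lines: one row per cell
#' line, one column per feature. Values must be complete (no `NA`); missing
#' molecular measurements are assumed to have been resolved upstream.
#'
#' @param values Numeric matrix, cell lines in rows, features in columns.
#' @param cell_line_ids Character vector of unique row labels. Defaults to
#'   `rownames(values)`.
#' @param feature_ids Character vector of unique column labels. Defaults to
#'   `colnames(values)`.
#' @return An object of class `feature_matrix`: a list with elements
#'   `values`, `cell_line_ids`, `feature_ids`.
#' @examples
#' X <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("c1", "c2", "c3"), c("g1", "g2")))
#' fm <- feature_matrix(X)
#' dim(fm)
#' @export
feature_matrix <- function(values, cell_line_ids = rownames(values),
                           feature_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("feature values must be numeric", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("feature matrix must not contain missing or non-finite values",
         call. = FALSE)
  }
  if (nrow(values) < 2L) {
    stop("a feature matrix needs at least 2 cell lines", call. = FALSE)
  }
  if (ncol(values) < 1L) {
    stop("a feature matrix needs at least 1 feature", call. = FALSE)
  }
  cell_line_ids <- check_ids(cell_line_ids, nrow(values), "cell line")
  feature_ids <- check_ids(feature_ids, ncol(values), "feature")
  dimnames(values) <- list(cell_line_ids, feature_ids)
  structure(list(values = values,
                 cell_line_ids = cell_line_ids,
                 feature_ids = feature_ids),
            class = "feature_matrix")
}

#' Construct a response matrix
#'
#' A response matrix holds one drug-response summary value (activity area,
#' AUC, -log10 GI50, ...) per cell line and drug, together with a logical
#' observation mask. Entries with `mask = FALSE` are treated as missing
#' everywhere downstream: they never enter a fit and realize the transductive
#' holdout geometry.
#'
#' @param values Numeric matrix, cell lines in rows, drugs (tasks) in
#'   columns. `NA` entries are recorded as unobserved.
#' @param mask Logical matrix of the same shape; `TRUE` marks an observed
#'   entry. Defaults to `!is.na(values)`.
#' @param cell_line_ids,drug_ids Row and column labels; default to the
#'   dimnames of `values`.
#' @return An object of class `response_matrix`: a list with elements
#'   `values`, `mask`, `cell_line_ids`, `drug_ids`.
#' @export
response_matrix <- function(values, mask = NULL,
                            cell_line_ids = rownames(values),
                            drug_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("response values must be numeric", call. = FALSE)
  }
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!identical(dim(mask), dim(values))) {
    stop("mask dimensions must match response values", call. = FALSE)
  }
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  if (any(is.na(values[mask]))) {
    stop("entries flagged observed must carry a numeric value", call. = FALSE)
  }
  cell_line_ids <- check_ids(cell_line_ids, nrow(values), "cell line")
  drug_ids <- check_ids(drug_ids, ncol(values), "drug")
  values[!mask] <- NA_real_
  dimnames(values) <- list(cell_line_ids, drug_ids)
  dimnames(mask) <- dimnames(values)
  empty <- colSums(mask) == 0L
  if (any(empty)) {
    warning("tasks with no observed responses: ",
            paste(drug_ids[empty], collapse = ", "), call. = FALSE)
  }
  structure(list(values = values, mask = mask,
                 cell_line_ids = cell_line_ids, drug_ids = drug_ids),
            class = "response_matrix")
}

check_ids <- function(ids, n, what) {
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) {
    stop(sprintf("expected %d %s ids, got %d", n, what, length(ids)),
         call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicated %s ids: %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  ids
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d cell lines x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d cell lines x %d drugs (%d observed of %d)\n",
              nrow(x$values), ncol(x$values), sum(x$mask), length(x$mask)))
  invisible(x)
}

as_feature_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) x else feature_matrix(x)
}

as_response_matrix <- function(y) {
  if (inherits(y, "response_matrix")) return(y)
  y <- as.matrix(y)
  response_matrix(y)
}

#' Align a feature matrix and a response matrix on shared cell lines
#'
#' Restricts both matrices to the intersection of their cell-line ids and
#' puts the rows in sorted-id order, so downstream cross-validation splits
#' are stable regardless of input row order.
#'
#' @param fm A [feature_matrix()].
#' @param rm A [response_matrix()].
#' @return A list with elements `features` and `responses`, both restricted
#'   to the common cell lines in identical sorted row order.
#' @export
align_matrices <- function(fm, rm) {
  fm <- as_feature_matrix(fm)
  rm <- as_response_matrix(rm)
  common <- sort(intersect(fm$cell_line_ids, rm$cell_line_ids))
  if (length(common) == 0L) {
    stop("feature and response matrices share no cell lines", call. = FALSE)
  }
  fm2 <- feature_matrix(fm$values[common, , drop = FALSE])
  rm2 <- response_matrix(rm$values[common, , drop = FALSE],
                         rm$mask[common, , drop = FALSE])
  list(features = fm2, responses = rm2)
}
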