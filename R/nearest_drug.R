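#' Nearest-drug-response-neighbor prediction
#'
#' A feature-free transductive baseline: to predict the response of drug
#' `d` on cell line `c`, find among the drugs with an observed training
#' response on `c` the one whose training response profile has the highest
#' Pearson correlation with `d` (computed on jointly observed training
#' cells, requiring at least `min_overlap` of them), then predict via the
#' univariate regression of `d` on that neighbor evaluated at the
#' neighbor's response on `c`. Cells where no admissible neighbor exists
#' fall back to the training mean of `d` and are flagged.
#'
#' Ties in the correlation are broken toward the lowest drug index. The
#' feature matrix is never consulted.
#'
#' @param Ytrain A [response_matrix()] holding only training observations
#'   (mask `FALSE` for held-out entries).
#' @param target_drug Drug id or column index to predict.
#' @param target_cells Integer row indices (or cell-line ids) to predict
#'   for.
#' @param min_overlap Minimum number of jointly observed training cells
#'   for a correlation/regression to be admissible (default 3).
#' @return List with `predictions` (named numeric vector over
#'   `target_cells`), `neighbor` (drug id used per cell, `NA` on
#'   fallback), and `fallback` (logical vector).
#' @export
nearest_drug_predict <- function(Ytrain, target_drug, target_cells,
                                 min_overlap = 3L) {
  Ytrain <- as_response_matrix(Ytrain)
  Yv <- Ytrain$values
  mask <- Ytrain$mask
  T_ <- ncol(Yv)
  if (T_ < 2L) stop("need at least 2 drugs", call. = FALSE)
  d <- if (is.character(target_drug)) {
    match(target_drug, Ytrain$drug_ids)
  } else as.integer(target_drug)
  if (is.na(d) || d < 1L || d > T_) {
    stop("unknown target drug", call. = FALSE)
  }
  if (is.character(target_cells)) {
    target_cells <- match(target_cells, Ytrain$cell_line_ids)
  }
  target_cells <- as.integer(target_cells)
  yd <- Yv[, d]
  obs_d <- mask[, d]
  if (!any(obs_d)) stop("target drug has no training observations",
                        call. = FALSE)
  mean_d <- mean(yd[obs_d])

  # admissible correlations of every drug with d on joint training cells
  r <- rep(-Inf, T_)
  coefs <- matrix(NA_real_, T_, 2L)  # intercept, slope of d ~ neighbor
  for (j in seq_len(T_)) {
    if (j == d) next
    joint <- obs_d & mask[, j]
    if (sum(joint) < min_overlap) next
    yj <- Yv[joint, j]
    ydj <- yd[joint]
    if (stats::sd(yj) == 0) next
    rj <- suppressWarnings(stats::cor(ydj, yj))
    if (is.na(rj)) rj <- 0
    r[j] <- rj
    slope <- stats::cov(ydj, yj) / stats::var(yj)
    coefs[j, ] <- c(mean(ydj) - slope * mean(yj), slope)
  }

  preds <- numeric(length(target_cells))
  neighbor <- rep(NA_character_, length(target_cells))
  fallback <- logical(length(target_cells))
  for (i in seq_along(target_cells)) {
    c_ <- target_cells[i]
    cand <- which(mask[c_, ] & seq_len(T_) != d & is.finite(r))
    if (length(cand) == 0L) {
      preds[i] <- mean_d
      fallback[i] <- TRUE
      next
    }
    j <- cand[which.max(r[cand])]
    preds[i] <- coefs[j, 1L] + coefs[j, 2L] * Yv[c_, j]
    neighbor[i] <- Ytrain$drug_ids[j]
  }
  names(preds) <- Ytrain$cell_line_ids[target_cells]
  list(predictions = preds, neighbor = neighbor, fallback = fallback)
}
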