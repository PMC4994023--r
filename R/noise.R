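#' Permutation-based label-noise test for one drug
#'
#' Asks whether elastic-net models trained on a drug's true response labels
#' predict held-out responses better than models trained on permuted
#' labels. Each real replicate draws a fresh random 80/20 train/test split
#' (splits are redrawn independently across replicates, so cells recur
#' across test sets), fits an elastic net on the training portion and
#' records test MSE; each permuted replicate first permutes the whole
#' response vector. The two MSE distributions are compared by a one-sided
#' Wilcoxon rank-sum test (real < permuted); a drug "passes" — its labels
#' carry signal — when the p-value falls below `threshold`.
#'
#' To keep the replicate loop affordable, the mixing parameter `alpha` is
#' selected once on the full data and each replicate selects only the
#' penalty, by a short cross-validated path on its training split.
#'
#' @param X Feature matrix ([feature_matrix()] or matrix).
#' @param y Numeric response vector for the drug.
#' @param R_real Replicates on true labels (default 200).
#' @param R_perm Replicates on permuted labels (default 1000; permuted
#'   MSE has higher variance).
#' @param holdout_frac Test fraction per replicate (default 0.2).
#' @param threshold Nominal significance threshold (default 0.01).
#' @param seed Integer seed.
#' @param alpha Optional fixed mixing parameter (skips selection).
#' @param n_lambda Length of the per-replicate penalty path (default 20).
#' @param inner_folds Folds of the per-replicate penalty selection
#'   (default 3).
#' @return Object of class `noise_report_entry`: list with `p_value`,
#'   `iqr` (response interquartile range), `pass`, `alpha`, `mse_real`,
#'   `mse_perm`.
#' @export
noise_test <- function(X, y, R_real = 200L, R_perm = 1000L,
                       holdout_frac = 0.2, threshold = 0.01, seed = 1L,
                       alpha = NULL, n_lambda = 20L, inner_folds = 3L) {
  X <- as_feature_matrix(X)$values
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(n == nrow(X), holdout_frac > 0, holdout_frac < 1)
  if (n < 10L) stop("need at least 10 samples", call. = FALSE)
  if (stats::sd(y) == 0) {
    stop("response is constant; noise test undefined", call. = FALSE)
  }
  local_seed(seed, {
    if (is.null(alpha)) {
      foldid <- sample(rep_len(seq_len(5L), n))
      cvms <- vapply(seq(0, 1, by = 0.1), function(al) {
        min(glmnet::cv.glmnet(X, y, alpha = al, foldid = foldid,
                              nlambda = 30L)$cvm)
      }, numeric(1L))
      alpha <- seq(0, 1, by = 0.1)[which.min(cvms)]
    }
    n_test <- max(1L, round(holdout_frac * n))
    one_mse <- function(yy) {
      te <- sample.int(n, n_test)
      tr <- setdiff(seq_len(n), te)
      lmax <- lambda_max_elastic_net(X[tr, , drop = FALSE], yy[tr],
                                     alpha)
      grid <- exp(seq(log(lmax), log(0.01 * lmax),
                      length.out = n_lambda))
      cv <- glmnet::cv.glmnet(X[tr, , drop = FALSE], yy[tr],
                              alpha = alpha, lambda = grid,
                              nfolds = inner_folds)
      pr <- stats::predict(cv, X[te, , drop = FALSE], s = "lambda.min")
      mean((yy[te] - pr)^2)
    }
    mse_real <- vapply(seq_len(R_real), function(i) one_mse(y),
                       numeric(1L))
    mse_perm <- vapply(seq_len(R_perm), function(i) {
      one_mse(sample(y))
    }, numeric(1L))
    p <- suppressWarnings(
      stats::wilcox.test(mse_real, mse_perm,
                         alternative = "less")$p.value)
    structure(list(p_value = p, iqr = stats::IQR(y),
                   pass = p < threshold, alpha = alpha,
                   mse_real = mse_real, mse_perm = mse_perm),
              class = "noise_report_entry")
  })
}

#' Summarize label-noise tests across drugs
#'
#' @param reports Named list of `noise_report_entry` objects, one per
#'   drug.
#' @param threshold Pass threshold (default 0.01).
#' @param p_grid Thresholds at which to report cumulative pass counts
#'   (for a pass-rate-versus-threshold curve).
#' @return List with `table` (data frame: drug_id, p_value, iqr, pass),
#'   `n_pass`, `n_total`, `pass_fraction`, `iqr_logp_cor` (Pearson
#'   correlation of response IQR with -log10 p across drugs), and
#'   `cumulative` (data frame over `p_grid`).
#' @export
noise_summary <- function(reports, threshold = 0.01,
                          p_grid = 10^seq(-10, 0, by = 0.25)) {
  stopifnot(length(reports) >= 2L)
  ids <- names(reports)
  if (is.null(ids)) ids <- as.character(seq_along(reports))
  p <- vapply(reports, `[[`, numeric(1L), "p_value")
  iqr <- vapply(reports, `[[`, numeric(1L), "iqr")
  pass <- p < threshold
  logp <- -log10(pmax(p, .Machine$double.xmin))
  r <- if (stats::sd(iqr) == 0 || stats::sd(logp) == 0) NA_real_
       else stats::cor(iqr, logp)
  list(table = data.frame(drug_id = ids, p_value = p, iqr = iqr,
                          pass = pass, row.names = NULL),
       n_pass = sum(pass), n_total = length(p),
       pass_fraction = mean(pass), iqr_logp_cor = r,
       cumulative = data.frame(threshold = p_grid,
                               n_pass = vapply(p_grid,
                                               function(th) sum(p < th),
                                               numeric(1L))))
}

#' Export a noise summary as TSV
#'
#' @param summary Result of [noise_summary()].
#' @param path Output path for the per-drug table.
#' @param curve_path Optional output path for the cumulative pass curve.
#' @return `path` invisibly.
#' @export
write_noise_report <- function(summary, path, curve_path = NULL) {
  utils::write.table(summary$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(curve_path)) {
    utils::write.table(summary$cumulative, curve_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
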