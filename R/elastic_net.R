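#' Elastic-net configuration
#'
#' Defaults follow the study design for single-task baselines: the mixing
#' parameter is searched over 11 values `{0, 0.1, ..., 1}` with the penalty
#' free along the path, then the penalty is re-optimized at the chosen
#' mixing value over 100 geometric values in `[0.01 lambda_max, lambda_max]`.
#'
#' @param alphas Mixing-parameter grid in `[0, 1]`.
#' @param n_lambda Number of penalty values on the final path.
#' @param min_ratio Smallest penalty as a fraction of `lambda_max`.
#' @param standardize Standardize features inside glmnet?
#' @return A list of class `elastic_net_config`.
#' @export
elastic_net_config <- function(alphas = seq(0, 1, by = 0.1),
                               n_lambda = 100L, min_ratio = 0.01,
                               standardize = TRUE) {
  stopifnot(all(alphas >= 0 & alphas <= 1), length(alphas) >= 1L,
            n_lambda >= 2L, min_ratio > 0, min_ratio < 1)
  structure(list(alphas = alphas, n_lambda = n_lambda,
                 min_ratio = min_ratio, standardize = standardize),
            class = "elastic_net_config")
}

#' Smallest elastic-net penalty with an all-zero slope vector
#'
#' `max_l |x_l' (y - mean(y))| / (N * alpha)` under the glmnet objective
#' `(1/2N) sum (y_i - w'x_i - b)^2 + lambda (alpha ||w||_1 +
#' (1-alpha)/2 ||w||_2^2)`, with columns standardized to unit
#' population variance when `standardize = TRUE`. For `alpha = 0` (pure
#' ridge, where no finite penalty zeroes the slopes) the conventional
#' surrogate `alpha = 0.001` is used to build a finite grid.
#'
#' @param X Feature matrix (or [feature_matrix()]).
#' @param y Numeric response vector.
#' @param alpha Mixing parameter in `[0, 1]`.
#' @param standardize Standardize columns before applying the formula?
#' @return A positive scalar.
#' @export
lambda_max_elastic_net <- function(X, y, alpha, standardize = TRUE) {
  X <- as_feature_matrix(X)$values
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X))
  if (stats::sd(y) == 0) {
    stop("response has zero variance; lambda_max undefined", call. = FALSE)
  }
  if (alpha <= 0) alpha <- 0.001
  n <- length(y)
  if (standardize) {
    ctr <- colMeans(X)
    scl <- sqrt(colMeans(sweep(X, 2L, ctr)^2))
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  }
  max(abs(drop(crossprod(X, y - mean(y))))) / (n * alpha)
}

#' Fit a single-task elastic-net model at fixed hyperparameters
#'
#' Solves the objective
#' `(1/2N) sum_i (y_i - w'x_i - b)^2 + lambda (alpha ||w||_1 +
#' (1 - alpha)/2 ||w||_2^2)` via [glmnet::glmnet()], with a short
#' decreasing path ending at `lambda` for a well-converged solution.
#'
#' glmnet standardizes the response internally, which silently rescales
#' the quadratic part of the penalty by `1/sd(y)` while leaving the L1
#' part intact; the call here reparameterizes `(alpha, lambda)` to undo
#' that, so the returned coefficients minimize the objective exactly as
#' written (the `alpha = 0` case agrees with the closed-form ridge
#' solution).
#'
#' @inheritParams lambda_max_elastic_net
#' @param lambda Penalty strength.
#' @return Object of class `single_task_model`: list with slope vector `w`,
#'   intercept `b`, `alpha`, `lambda`.
#' @export
fit_elastic_net <- function(X, y, alpha, lambda, standardize = TRUE) {
  X <- as_feature_matrix(X)$values
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), nrow(X) >= 2L, lambda >= 0,
            alpha >= 0, alpha <= 1)
  sy <- sqrt(mean((y - mean(y))^2))
  if (lambda > 0 && sy > 0) {
    # match glmnet's internal response scaling: effective L1 penalty is
    # lambda*alpha as given, effective L2 penalty is lambda*(1-alpha)/sy
    lam_eff <- lambda * alpha + lambda * (1 - alpha) * sy
    alpha_eff <- lambda * alpha / lam_eff
    lmax <- lambda_max_elastic_net(X, y, max(alpha_eff, 0.001),
                                   standardize)
    top <- max(lmax, lam_eff * 1.0001)
    path <- exp(seq(log(top), log(lam_eff), length.out = 15L))
  } else {
    lam_eff <- lambda
    alpha_eff <- alpha
    path <- lam_eff
  }
  fit <- glmnet::glmnet(X, y, alpha = alpha_eff, lambda = path,
                        standardize = standardize,
                        thresh = 1e-10, maxit = 1e6)
  cf <- stats::coef(fit, s = lam_eff, exact = FALSE)
  w <- as.numeric(cf)[-1L]
  names(w) <- colnames(X)
  structure(list(w = w, b = as.numeric(cf)[1L], alpha = alpha,
                 lambda = lambda),
            class = "single_task_model")
}

#' @export
predict.single_task_model <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)$values
  drop(X %*% object$w) + object$b
}

#' Select elastic-net hyperparameters by cross-validation
#'
#' Two-stage selection mirroring the single-task training protocol: the
#' mixing parameter `alpha` is chosen over its grid by K-fold
#' cross-validated mean squared error with the penalty free along each
#' path; then, at the chosen `alpha`, the penalty is re-optimized over
#' `n_lambda` geometric values in `[min_ratio * lambda_max, lambda_max]`.
#' Fold assignments are shared across all candidate values and are
#' deterministic given `seed`; penalty ties are broken toward the larger
#' (more regularized) value.
#'
#' @inheritParams lambda_max_elastic_net
#' @param config An [elastic_net_config()].
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return List with `alpha`, `lambda`, and `cvm` (the winning
#'   cross-validated MSE).
#' @export
select_alpha_lambda <- function(X, y, config = elastic_net_config(),
                                folds = 5L, seed = 1L) {
  X <- as_feature_matrix(X)$values
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L * folds) {
    stop(sprintf("%d samples is too few for %d-fold selection", n, folds),
         call. = FALSE)
  }
  foldid <- local_seed(seed, sample(rep_len(seq_len(folds), n)))
  best <- list(alpha = NA_real_, cvm = Inf)
  for (al in config$alphas) {
    cv <- glmnet::cv.glmnet(X, y, alpha = al, foldid = foldid,
                            standardize = config$standardize,
                            nlambda = 50L)
    m <- min(cv$cvm)
    if (m < best$cvm) best <- list(alpha = al, cvm = m)
  }
  alpha <- best$alpha
  lmax <- lambda_max_elastic_net(X, y, alpha, config$standardize)
  grid <- exp(seq(log(lmax), log(config$min_ratio * lmax),
                  length.out = config$n_lambda))
  cv <- glmnet::cv.glmnet(X, y, alpha = alpha, lambda = grid,
                          foldid = foldid,
                          standardize = config$standardize)
  # cv$lambda is decreasing, so the first minimum is the largest lambda
  lambda <- cv$lambda[which.min(cv$cvm)]
  list(alpha = alpha, lambda = lambda, cvm = min(cv$cvm))
}

# evaluate expr under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
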