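#' Specification for the synthetic low-rank multitask generator
#'
#' The generator emulates the structure the trace-norm method assumes in
#' drug-response panels: a feature matrix mixing continuous (expression /
#' copy-number-like, standard normal) columns with sparse binary
#' (mutation-like) columns, a true coefficient matrix of exact low rank
#' shared across tasks, additive Gaussian response noise, and an optional
#' fraction of "noisy drugs" whose response column is permuted so that it
#' carries no signal. Optionally, tasks can be organized into mechanism
#' groups whose task-side factors are shared (plus jitter), giving a
#' ground-truth partition for clustering analyses.
#'
#' @param N,P,T Number of cell lines, features and tasks (drugs).
#' @param rank Exact rank of the true coefficient matrix (before any task
#'   permutation), at most `min(P, T)`.
#' @param group_assignment Optional length-`T` vector of mechanism-group
#'   labels; tasks in the same group share task-side factors up to
#'   `group_jitter`.
#' @param noise_sd Standard deviation of additive response noise; signal
#'   variance is calibrated to ~1 per task, so this is roughly a
#'   noise-to-signal ratio.
#' @param frac_binary_features Fraction of feature columns that are binary.
#' @param binary_prevalence Bernoulli rate of the binary columns (default
#'   0.1, mimicking mutation sparsity).
#' @param frac_noisy_tasks Fraction of tasks whose responses are permuted.
#' @param group_jitter Relative sd of the within-group factor jitter.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(N = 100L, P = 50L, T = 20L, rank = 2L,
                           group_assignment = NULL, noise_sd = 0.5,
                           frac_binary_features = 0.2,
                           binary_prevalence = 0.1,
                           frac_noisy_tasks = 0, group_jitter = 0.1,
                           seed = 1L) {
  stopifnot(N >= 2L, P >= 1L, T >= 1L, rank >= 1L, rank <= min(P, T),
            noise_sd >= 0, frac_binary_features >= 0,
            frac_binary_features <= 1, binary_prevalence > 0,
            binary_prevalence < 1, frac_noisy_tasks >= 0,
            frac_noisy_tasks <= 1)
  if (!is.null(group_assignment) && length(group_assignment) != T) {
    stop("group_assignment must have one label per task", call. = FALSE)
  }
  structure(list(N = N, P = P, T = T, rank = rank,
                 group_assignment = group_assignment, noise_sd = noise_sd,
                 frac_binary_features = frac_binary_features,
                 binary_prevalence = binary_prevalence,
                 frac_noisy_tasks = frac_noisy_tasks,
                 group_jitter = group_jitter, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic multitask drug-response data set
#'
#' See [synthetic_spec()] for the generating model. The true coefficient
#' matrix is `U V'` with Gaussian factors, rescaled so that the average
#' per-task signal variance (using the theoretical feature variances) is 1;
#' responses are `Y = X W + 1 b' + eps` with `eps ~ N(0, noise_sd^2)`.
#' Tasks flagged noisy have their finished response column independently
#' permuted, destroying any feature-response association while preserving
#' the marginal distribution.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `features` (a [feature_matrix()]), `responses` (a
#'   fully observed [response_matrix()]), and `truth` (list: `W_true`,
#'   `b_true`, `noisy_task_ids`, `group_assignment`).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  local_seed(spec$seed, {
    N <- spec$N; P <- spec$P; T_ <- spec$T; r <- spec$rank
    n_bin <- round(spec$frac_binary_features * P)
    is_bin <- rep(FALSE, P)
    if (n_bin > 0L) is_bin[sample.int(P, n_bin)] <- TRUE
    X <- matrix(rnorm(N * P), N, P)
    if (n_bin > 0L) {
      X[, is_bin] <- matrix(
        as.numeric(runif(N * n_bin) < spec$binary_prevalence), N, n_bin)
    }
    U <- matrix(rnorm(P * r), P, r)
    if (is.null(spec$group_assignment)) {
      V <- matrix(rnorm(T_ * r), T_, r)
    } else {
      groups <- as.character(spec$group_assignment)
      proto <- matrix(rnorm(length(unique(groups)) * r),
                      length(unique(groups)), r,
                      dimnames = list(unique(groups), NULL))
      V <- proto[groups, , drop = FALSE] +
        spec$group_jitter * matrix(rnorm(T_ * r), T_, r)
    }
    W <- U %*% t(V)
    feat_var <- ifelse(is_bin,
                       spec$binary_prevalence * (1 - spec$binary_prevalence),
                       1)
    sig <- mean(colSums(W^2 * feat_var))
    if (sig > 0) W <- W / sqrt(sig)
    b <- rnorm(T_)
    Y <- X %*% W + matrix(b, N, T_, byrow = TRUE)
    if (spec$noise_sd > 0) {
      Y <- Y + matrix(rnorm(N * T_, sd = spec$noise_sd), N, T_)
    }
    n_noisy <- round(spec$frac_noisy_tasks * T_)
    noisy <- if (n_noisy > 0L) sort(sample.int(T_, n_noisy)) else integer(0)
    for (t in noisy) Y[, t] <- Y[sample.int(N), t]
    cell_ids <- sprintf("cell_%03d", seq_len(N))
    feat_ids <- sprintf("feat_%04d", seq_len(P))
    drug_ids <- sprintf("drug_%02d", seq_len(T_))
    dimnames(X) <- list(cell_ids, feat_ids)
    dimnames(Y) <- list(cell_ids, drug_ids)
    dimnames(W) <- list(feat_ids, drug_ids)
    list(features = feature_matrix(X),
         responses = response_matrix(Y),
         truth = list(W_true = W, b_true = stats::setNames(b, drug_ids),
                      noisy_task_ids = drug_ids[noisy],
                      group_assignment = spec$group_assignment))
  })
}

#' Hold out a fraction of responses in inductive or transductive geometry
#'
#' Inductive holdout removes whole cell lines: the same `round(frac * N)`
#' rows are masked across every task. Transductive holdout independently
#' masks `round(frac * n_obs)` of each task's observed entries, so
#' different cells are hidden for different drugs. Held-out entries are
#' recoverable by comparing masks with the input.
#'
#' @param rm A [response_matrix()].
#' @param frac Fraction to hold out, in (0, 1).
#' @param mode `"inductive"` or `"transductive"`.
#' @param seed Integer seed.
#' @return A [response_matrix()] with the held-out entries unobserved.
#' @export
holdout_mask <- function(rm, frac, mode = c("transductive", "inductive"),
                         seed = 1L) {
  rm <- as_response_matrix(rm)
  mode <- match.arg(mode)
  stopifnot(frac > 0, frac < 1)
  mask <- rm$mask
  local_seed(seed, {
    if (mode == "inductive") {
      n_hold <- round(frac * nrow(mask))
      rows <- sample.int(nrow(mask), n_hold)
      mask[rows, ] <- FALSE
    } else {
      for (t in seq_len(ncol(mask))) {
        obs <- which(mask[, t])
        n_hold <- round(frac * length(obs))
        if (n_hold > 0L) mask[sample(obs, n_hold), t] <- FALSE
      }
    }
  })
  if (any(colSums(mask) == 0L)) {
    stop("holdout leaves at least one task with no training responses",
         call. = FALSE)
  }
  vals <- rm$values
  vals[!mask] <- NA_real_
  response_matrix(vals, mask, rm$cell_line_ids, rm$drug_ids)
}
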