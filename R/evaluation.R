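#' Build a K-fold split plan in inductive or transductive geometry
#'
#' Inductive plans hold out the same cell lines across every task: the rows
#' are partitioned once into `k` folds and each task's fold-`f` test set is
#' its observed entries among the fold-`f` rows. Transductive plans draw an
#' independent `k`-fold partition of each task's observed entries, so
#' different cells are held out for different drugs while the full feature
#' matrix stays visible to the learner.
#'
#' @param rm A [response_matrix()].
#' @param mode `"transductive"` or `"inductive"`.
#' @param k Number of folds (default 5, i.e. 80% train / 20% test).
#' @param seed Integer seed; the plan is deterministic given it.
#' @return Object of class `split_plan`: list with `mode`, `k`, `seed`,
#'   `n`, `drug_ids`, and `test` — a list over folds, each a list over
#'   tasks of held-out row indices.
#' @export
make_split_plan <- function(rm, mode = c("transductive", "inductive"),
                            k = 5L, seed = 1L) {
  rm <- as_response_matrix(rm)
  mode <- match.arg(mode)
  k <- as.integer(k)
  stopifnot(k >= 2L)
  mask <- rm$mask
  T_ <- ncol(mask)
  n_obs <- colSums(mask)
  small <- n_obs < k
  if (any(small)) {
    stop(sprintf("tasks with fewer than %d observed responses: %s", k,
                 paste(rm$drug_ids[small], collapse = ", ")),
         call. = FALSE)
  }
  if (any(n_obs < 5L)) {
    stop("each task needs at least 5 observed responses for cross-validation",
         call. = FALSE)
  }
  test <- local_seed(seed, {
    if (mode == "inductive") {
      fold_of_row <- sample(rep_len(seq_len(k), nrow(mask)))
      lapply(seq_len(k), function(f) {
        rows <- which(fold_of_row == f)
        lapply(seq_len(T_), function(t) rows[mask[rows, t]])
      })
    } else {
      fold_of <- lapply(seq_len(T_), function(t) {
        obs <- which(mask[, t])
        stats::setNames(sample(rep_len(seq_len(k), length(obs))), obs)
      })
      lapply(seq_len(k), function(f) {
        lapply(seq_len(T_), function(t) {
          as.integer(names(fold_of[[t]])[fold_of[[t]] == f])
        })
      })
    }
  })
  structure(list(mode = mode, k = k, seed = seed, n = nrow(mask),
                 drug_ids = rm$drug_ids, test = test),
            class = "split_plan")
}

#' Serialize / restore a split plan as JSON
#'
#' Enables reuse of identical train/test index sets across learners, which
#' paired model comparisons require.
#'
#' @param plan A [make_split_plan()] object.
#' @param path Output (or input) file path.
#' @return `path` invisibly; `read_split_plan` returns the plan.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  p$test <- lapply(p$test, function(f) {
    lapply(f, function(idx) vapply(idx, as.integer, integer(1L)))
  })
  p$mode <- as.character(p$mode)
  p$k <- as.integer(p$k)
  p$seed <- as.integer(p$seed)
  p$n <- as.integer(p$n)
  p$drug_ids <- vapply(p$drug_ids, as.character, character(1L))
  structure(p, class = "split_plan")
}

# training mask for one outer fold: observed minus that fold's test entries
training_mask <- function(mask, plan, fold) {
  for (t in seq_len(ncol(mask))) {
    mask[plan$test[[fold]][[t]], t] <- FALSE
  }
  mask
}

#' Nested K-fold cross-validation for multitask and single-task learners
#'
#' For each outer fold of `plan`, hyperparameters are selected by an inner
#' cross-validation run entirely on that fold's training entries, the model
#' is refit on the full training entries at the selected values, and the
#' held-out entries are scored by mean squared error per task.
#'
#' Learners:
#' \describe{
#'   \item{`trace_norm`}{One joint model per fold. The penalty grid is
#'     anchored at the training-data [lambda_max_trace_norm()]; inner folds
#'     preserve the plan's geometry (per-task entry splits in transductive
#'     mode, row splits in inductive mode); the penalty minimizing pooled
#'     inner validation MSE is chosen, ties broken toward the larger
#'     value. In transductive mode the learner sees the whole feature
#'     matrix and the training-masked response matrix.}
#'   \item{`elastic_net`}{One model per task. The mixing parameter is
#'     chosen on the training rows over `config$alphas` with the penalty
#'     free, then the penalty is re-optimized on a geometric grid (see
#'     [select_alpha_lambda()]); set `fixed_alpha` to skip the first
#'     stage.}
#'   \item{`mean`}{Predicts each task's training mean (a floor for sanity
#'     checks).}
#' }
#'
#' @param X A [feature_matrix()] (or matrix) aligned with `Y`.
#' @param Y A [response_matrix()] (or matrix with `NA`s).
#' @param plan A [make_split_plan()] built from `Y`.
#' @param learner `"trace_norm"`, `"elastic_net"` or `"mean"`.
#' @param inner_k Inner folds for hyperparameter selection (default 5).
#' @param n_lambda,min_ratio Trace-norm penalty grid shape.
#' @param rho,tol_abs,tol_rel,max_iter,standardize ADMM controls, see
#'   [fit_trace_norm()].
#' @param config An [elastic_net_config()].
#' @param fixed_alpha Optional fixed elastic-net mixing parameter.
#' @param folds Which outer folds to evaluate (default all). Evaluating a
#'   single fold of a 5-fold plan gives an 80/20 holdout estimate at a
#'   fifth of the cost; untouched folds yield `NA` in `fold_mse`.
#' @return Object of class `cv_result`: list with `learner`, `mode`,
#'   `drug_ids`, `fold_mse` (T x k matrix), `mean_mse` (per-task vector),
#'   `selected` (per-fold hyperparameters), `plan_seed`.
#' @export
nested_cv <- function(X, Y, plan, learner = c("trace_norm", "elastic_net",
                                              "mean"),
                      inner_k = 5L, n_lambda = 50L, min_ratio = 0.01,
                      rho = 1, tol_abs = 1e-4, tol_rel = 1e-3,
                      max_iter = 2000L, standardize = TRUE,
                      config = elastic_net_config(), fixed_alpha = NULL,
                      folds = seq_len(plan$k)) {
  learner <- match.arg(learner)
  X <- as_feature_matrix(X)
  Y <- as_response_matrix(Y)
  stopifnot(inherits(plan, "split_plan"), plan$n == nrow(Y$values),
            length(plan$drug_ids) == ncol(Y$values))
  T_ <- ncol(Y$values)
  k <- plan$k
  fold_mse <- matrix(NA_real_, T_, k,
                     dimnames = list(Y$drug_ids, paste0("fold", seq_len(k))))
  selected <- vector("list", k)
  stopifnot(all(folds %in% seq_len(k)))
  for (f in folds) {
    tr_mask <- training_mask(Y$mask, plan, f)
    # leakage guard: no held-out entry may remain in the training mask
    for (t in seq_len(T_)) {
      if (any(tr_mask[plan$test[[f]][[t]], t])) {
        stop("leakage: test entry present in training mask", call. = FALSE)
      }
    }
    Ytr <- response_matrix(ifelse(tr_mask, Y$values, NA_real_), tr_mask,
                           Y$cell_line_ids, Y$drug_ids)
    preds <- switch(learner,
      trace_norm = {
        res <- cv_fit_trace_norm(X, Ytr, plan$mode, inner_k,
                                 seed = plan$seed + 7919L * f,
                                 n_lambda = n_lambda,
                                 min_ratio = min_ratio, rho = rho,
                                 tol_abs = tol_abs, tol_rel = tol_rel,
                                 max_iter = max_iter,
                                 standardize = standardize)
        selected[[f]] <- list(lambda = res$lambda)
        predict(res$model, X)
      },
      elastic_net = {
        res <- cv_fit_elastic_net(X, Ytr, plan$test[[f]],
                                  seed = plan$seed + 7919L * f,
                                  inner_k = inner_k, config = config,
                                  fixed_alpha = fixed_alpha)
        selected[[f]] <- res$selected
        res$pred
      },
      mean = {
        mu <- vapply(seq_len(T_), function(t) {
          mean(Ytr$values[Ytr$mask[, t], t])
        }, numeric(1L))
        selected[[f]] <- list()
        matrix(mu, nrow(Y$values), T_, byrow = TRUE)
      })
    for (t in seq_len(T_)) {
      te <- plan$test[[f]][[t]]
      if (length(te)) {
        fold_mse[t, f] <- mean((Y$values[te, t] - preds[te, t])^2)
      }
    }
  }
  structure(list(learner = learner, mode = plan$mode,
                 drug_ids = Y$drug_ids, fold_mse = fold_mse,
                 mean_mse = rowMeans(fold_mse, na.rm = TRUE),
                 selected = selected, plan_seed = plan$seed),
            class = "cv_result")
}

# inner-CV penalty selection + refit for the trace-norm learner
cv_fit_trace_norm <- function(X, Ytr, mode, inner_k, seed, n_lambda,
                              min_ratio, rho, tol_abs, tol_rel, max_iter,
                              standardize) {
  designs <- admm_designs(X, Ytr, standardize)
  lmax <- lambda_max_trace_norm(designs)
  grid <- trace_lambda_grid(lmax, n_lambda, min_ratio)
  inner_plan <- make_split_plan(Ytr, mode, k = inner_k, seed = seed)
  T_ <- ncol(Ytr$values)
  sse <- numeric(length(grid))
  n_val <- 0L
  for (g in seq_len(inner_k)) {
    in_mask <- training_mask(Ytr$mask, inner_plan, g)
    Yin <- response_matrix(ifelse(in_mask, Ytr$values, NA_real_), in_mask,
                           Ytr$cell_line_ids, Ytr$drug_ids)
    path <- fit_trace_norm_path(X, Yin, lambdas = grid, rho = rho,
                                tol_abs = tol_abs, tol_rel = tol_rel,
                                max_iter = max_iter,
                                standardize = standardize)
    for (i in seq_along(grid)) {
      pr <- predict(path[[i]], X)
      for (t in seq_len(T_)) {
        val <- inner_plan$test[[g]][[t]]
        if (length(val)) {
          sse[i] <- sse[i] + sum((Ytr$values[val, t] - pr[val, t])^2)
        }
      }
    }
    n_val <- n_val + sum(lengths(inner_plan$test[[g]]))
  }
  best <- which.min(sse)  # grid is decreasing: first min = larger lambda
  path <- fit_trace_norm_path(X, Ytr, lambdas = grid[seq_len(best)],
                              rho = rho, tol_abs = tol_abs,
                              tol_rel = tol_rel, max_iter = max_iter,
                              standardize = standardize,
                              designs = designs)
  list(model = path[[best]], lambda = grid[best],
       cv_mse = sse[best] / n_val)
}

#' Select the trace-norm penalty by cross-validation and refit on all data
#'
#' Optimizes the penalty over its geometric grid by K-fold
#' cross-validation (in the requested geometry) on the supplied data, then
#' refits on every observed entry at the selected value — the protocol
#' used to produce a final coefficient matrix for interpretation after
#' hyperparameters have been validated.
#'
#' @inheritParams nested_cv
#' @param mode Split geometry for the selection folds.
#' @param k Number of selection folds (default 5).
#' @param seed Integer seed for the fold draw.
#' @return List with `model` (a `multitask_model` trained on all observed
#'   entries), `lambda`, and `cv_mse` (pooled validation MSE at the
#'   selected penalty).
#' @export
fit_trace_norm_cv <- function(X, Y, mode = c("transductive", "inductive"),
                              k = 5L, seed = 1L, n_lambda = 50L,
                              min_ratio = 0.01, rho = 1, tol_abs = 1e-4,
                              tol_rel = 1e-3, max_iter = 2000L,
                              standardize = TRUE) {
  mode <- match.arg(mode)
  X <- as_feature_matrix(X)
  Y <- as_response_matrix(Y)
  cv_fit_trace_norm(X, Y, mode, inner_k = k, seed = seed,
                    n_lambda = n_lambda, min_ratio = min_ratio, rho = rho,
                    tol_abs = tol_abs, tol_rel = tol_rel,
                    max_iter = max_iter, standardize = standardize)
}

# per-task alpha/lambda selection + refit for the elastic-net learner
cv_fit_elastic_net <- function(X, Ytr, test_sets, seed, inner_k, config,
                               fixed_alpha) {
  Xv <- X$values
  T_ <- ncol(Ytr$values)
  pred <- matrix(NA_real_, nrow(Xv), T_)
  selected <- vector("list", T_)
  for (t in seq_len(T_)) {
    idx <- which(Ytr$mask[, t])
    yt <- Ytr$values[idx, t]
    Xt <- Xv[idx, , drop = FALSE]
    cfg <- config
    if (!is.null(fixed_alpha)) cfg$alphas <- fixed_alpha
    sel <- select_alpha_lambda(Xt, yt, cfg, folds = inner_k,
                               seed = seed + t)
    fit <- fit_elastic_net(Xt, yt, sel$alpha, sel$lambda,
                           standardize = cfg$standardize)
    pred[, t] <- predict(fit, Xv)
    selected[[t]] <- list(alpha = sel$alpha, lambda = sel$lambda)
  }
  list(pred = pred, selected = selected)
}

#' Paired comparison of two cross-validation results
#'
#' Tests whether method A achieves lower per-task mean squared error than
#' method B with a one-sided Wilcoxon signed-rank test over tasks (exact
#' distribution when there are at most 25 informative tasks and no ties,
#' normal approximation with continuity correction otherwise), and reports
#' per-task wins/losses and the mean percent MSE reduction.
#'
#' @param a,b `cv_result` objects from [nested_cv()] computed on the same
#'   plan (identical tasks and folds).
#' @return Object of class `comparison_report`: list with `delta`
#'   (per-task `A - B` mean MSE), `wins`, `losses`, `ties`, `p_value`
#'   (one-sided, A < B), `pct_reduction` (mean over tasks of
#'   `(B - A)/B * 100`).
#' @export
compare_paired <- function(a, b) {
  stopifnot(inherits(a, "cv_result"), inherits(b, "cv_result"))
  if (!identical(a$drug_ids, b$drug_ids) ||
      !identical(dim(a$fold_mse), dim(b$fold_mse))) {
    stop("cv results cover different tasks or folds", call. = FALSE)
  }
  ma <- a$mean_mse
  mb <- b$mean_mse
  d <- ma - mb
  wins <- sum(d < 0)
  losses <- sum(d > 0)
  ties <- sum(d == 0)
  p <- if (all(d == 0)) {
    1
  } else {
    nz <- d[d != 0]
    exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
    suppressWarnings(
      stats::wilcox.test(ma, mb, paired = TRUE, alternative = "less",
                         exact = exact, correct = TRUE)$p.value)
  }
  structure(list(delta = d, wins = wins, losses = losses, ties = ties,
                 p_value = p,
                 pct_reduction = mean((mb - ma) / mb * 100)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(paste0("comparison_report: %d wins, %d losses, %d ties; ",
                     "one-sided signed-rank P = %.3g; mean MSE reduction ",
                     "%.1f%%\n"),
              x$wins, x$losses, x$ties, x$p_value, x$pct_reduction))
  invisible(x)
}

#' Effect of the number of jointly trained tasks on multitask accuracy
#'
#' Randomly partitions the tasks into consecutive groups of each requested
#' size (a smaller remainder group is allowed), fits a transductive
#' trace-norm model per group with nested cross-validation, and records
#' each task's mean MSE exactly once per group size. Shrinking the groups
#' isolates how much of the multitask advantage comes from sharing across
#' many tasks.
#'
#' @param X,Y Aligned feature and response matrices.
#' @param group_sizes Integer vector of group sizes to evaluate, each at
#'   most the number of tasks.
#' @param seed Integer seed controlling both the task partition and the
#'   split plans.
#' @param k,inner_k Outer/inner fold counts.
#' @param n_lambda,min_ratio,standardize Trace-norm controls (reduced grid
#'   by default; many small fits are run).
#' @return A data frame with columns `group_size`, `drug_id`, `mse`.
#' @export
task_group_ablation <- function(X, Y, group_sizes, seed = 1L, k = 5L,
                                inner_k = 3L, n_lambda = 20L,
                                min_ratio = 0.01, standardize = TRUE) {
  X <- as_feature_matrix(X)
  Y <- as_response_matrix(Y)
  T_ <- ncol(Y$values)
  stopifnot(all(group_sizes >= 1L), all(group_sizes <= T_))
  out <- list()
  for (g in group_sizes) {
    perm <- local_seed(seed + g, sample.int(T_))
    groups <- split(perm, ceiling(seq_along(perm) / g))
    groups <- lapply(groups, sort)  # original column order within groups
    for (gr in groups) {
      Ysub <- response_matrix(Y$values[, gr, drop = FALSE],
                              Y$mask[, gr, drop = FALSE],
                              Y$cell_line_ids, Y$drug_ids[gr])
      plan <- make_split_plan(Ysub, "transductive", k = k, seed = seed)
      res <- nested_cv(X, Ysub, plan, "trace_norm", inner_k = inner_k,
                       n_lambda = n_lambda, min_ratio = min_ratio,
                       standardize = standardize)
      out[[length(out) + 1L]] <- data.frame(group_size = g,
                                            drug_id = Ysub$drug_ids,
                                            mse = unname(res$mean_mse))
    }
  }
  do.call(rbind, out)
}

#' Export a cross-validation result as TSV
#'
#' @param x A `cv_result`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_cv_result <- function(x, path) {
  df <- data.frame(drug_id = x$drug_ids, x$fold_mse,
                   mean_mse = x$mean_mse, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
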