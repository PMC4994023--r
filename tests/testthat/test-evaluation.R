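small_panel <- function(seed = 1, N = 30L, T_ = 3L) {
  generate_synthetic(synthetic_spec(N = N, P = 8L, T = T_, rank = 2L,
                                    noise_sd = 0.5, seed = seed))
}

test_that("inductive plans hold out the same rows across tasks", {
  dat <- small_panel(N = 10L)
  plan <- make_split_plan(dat$responses, "inductive", k = 5, seed = 3)
  for (f in 1:5) {
    sizes <- lengths(plan$test[[f]])
    expect_true(all(sizes == 2L))
    rows <- unique(plan$test[[f]])
    expect_length(rows, 1L)  # identical across tasks
  }
  # folds partition each task's observed entries
  for (t in 1:3) {
    all_rows <- sort(unlist(lapply(plan$test, `[[`, t)))
    expect_identical(all_rows, 1:10)
  }
})

test_that("transductive plans differ across tasks and are seed-stable", {
  dat <- small_panel(N = 25L, T_ = 3L)
  differs <- vapply(1:5, function(s) {
    plan <- make_split_plan(dat$responses, "transductive", k = 5, seed = s)
    any(vapply(1:5, function(f) {
      length(unique(plan$test[[f]])) > 1L
    }, logical(1)))
  }, logical(1))
  expect_true(any(differs))

  p1 <- make_split_plan(dat$responses, "transductive", k = 5, seed = 42)
  p2 <- make_split_plan(dat$responses, "transductive", k = 5, seed = 42)
  expect_identical(p1, p2)

  # round trip through JSON preserves the plan
  path <- withr::local_tempfile(fileext = ".json")
  write_split_plan(p1, path)
  expect_identical(read_split_plan(path)$test, p1$test)
})

test_that("tiny tasks are rejected with the task named", {
  Yv <- cbind(rnorm(10), c(rnorm(4), rep(NA, 6)))
  colnames(Yv) <- c("ok_drug", "tiny_drug")
  rownames(Yv) <- sprintf("c%d", 1:10)
  rm_ <- suppressWarnings(response_matrix(Yv))
  expect_error(make_split_plan(rm_, "transductive", k = 5),
               "tiny_drug")
})

test_that("mean learner scores match hand-computed test variances", {
  set.seed(8)
  Yv <- matrix(rnorm(20), 10, 2,
               dimnames = list(sprintf("c%d", 1:10), c("d1", "d2")))
  Xv <- matrix(rnorm(30), 10, 3,
               dimnames = list(rownames(Yv), c("g1", "g2", "g3")))
  rm_ <- response_matrix(Yv)
  plan <- make_split_plan(rm_, "inductive", k = 5, seed = 1)
  res <- nested_cv(Xv, rm_, plan, "mean")
  for (f in 1:5) {
    for (t in 1:2) {
      te <- plan$test[[f]][[t]]
      tr <- setdiff(1:10, te)
      expect_equal(res$fold_mse[t, f],
                   mean((Yv[te, t] - mean(Yv[tr, t]))^2),
                   tolerance = 1e-12)
    }
  }
})

test_that("near-noiseless low-rank data is fit almost perfectly", {
  dat <- generate_synthetic(synthetic_spec(N = 60L, P = 10L, T = 4L,
                                           rank = 2L, noise_sd = 1e-4,
                                           seed = 12))
  plan <- make_split_plan(dat$responses, "transductive", k = 5, seed = 2)
  res <- nested_cv(dat$features, dat$responses, plan, "trace_norm",
                   inner_k = 3, n_lambda = 25L, min_ratio = 1e-4,
                   folds = 1L)
  expect_lt(mean(res$fold_mse[, 1]), 1e-3)
})

test_that("flipping held-out responses cannot change selected hyperparameters", {
  dat <- small_panel(seed = 6, N = 40L)
  plan <- make_split_plan(dat$responses, "transductive", k = 5, seed = 9)
  res1 <- nested_cv(dat$features, dat$responses, plan, "trace_norm",
                    inner_k = 3, n_lambda = 10L, folds = 1L)
  Yv <- dat$responses$values
  for (t in seq_len(ncol(Yv))) {
    Yv[plan$test[[1]][[t]], t] <- -5 * Yv[plan$test[[1]][[t]], t] + 3
  }
  Y2 <- response_matrix(Yv, dat$responses$mask,
                        dat$responses$cell_line_ids,
                        dat$responses$drug_ids)
  res2 <- nested_cv(dat$features, Y2, plan, "trace_norm",
                    inner_k = 3, n_lambda = 10L, folds = 1L)
  expect_identical(res1$selected[[1]], res2$selected[[1]])
})

test_that("shared plans give identical test sets to both learners", {
  dat <- small_panel(seed = 2, N = 30L)
  plan <- make_split_plan(dat$responses, "transductive", k = 5, seed = 4)
  a <- nested_cv(dat$features, dat$responses, plan, "mean")
  b <- nested_cv(dat$features, dat$responses, plan, "mean")
  expect_identical(a$fold_mse, b$fold_mse)
})

test_that("paired comparison counts wins and computes signed-rank p", {
  base <- list(learner = "a", mode = "transductive",
               drug_ids = sprintf("d%d", 1:20),
               fold_mse = matrix(1, 20, 5), mean_mse = rep(1, 20),
               selected = list(), plan_seed = 1L)
  class(base) <- "cv_result"
  same <- compare_paired(base, base)
  expect_equal(same$wins, 0)
  expect_equal(same$losses, 0)
  expect_gte(same$p_value, 0.5)

  better <- base
  set.seed(13)
  better$mean_mse <- base$mean_mse * 0.9 * runif(20, 0.99, 1.01)
  better$fold_mse <- matrix(better$mean_mse, 20, 5)
  cmp <- compare_paired(better, base)
  expect_equal(cmp$wins, 20)
  expect_lt(cmp$p_value, 0.001)
  # exact one-sided signed-rank floor for n = 20, all negative: 2^-20
  expect_equal(cmp$p_value, 2^-20, tolerance = 1e-10)
  expect_equal(cmp$pct_reduction,
               mean((base$mean_mse - better$mean_mse) / base$mean_mse) * 100)

  single <- base
  single$drug_ids <- "d1"
  single$fold_mse <- matrix(0.5, 1, 5)
  single$mean_mse <- 0.5
  other <- single
  other$mean_mse <- 1
  other$fold_mse <- matrix(1, 1, 5)
  expect_equal(compare_paired(single, other)$p_value, 0.5)

  expect_error(compare_paired(base, single), "different tasks")
})

test_that("a single task group reproduces the full multitask run", {
  dat <- generate_synthetic(synthetic_spec(N = 40L, P = 10L, T = 4L,
                                           rank = 2L, seed = 31))
  tab <- task_group_ablation(dat$features, dat$responses,
                             group_sizes = 4L, seed = 5, k = 3,
                             inner_k = 2, n_lambda = 8L)
  plan <- make_split_plan(dat$responses, "transductive", k = 3, seed = 5)
  direct <- nested_cv(dat$features, dat$responses, plan, "trace_norm",
                      inner_k = 2, n_lambda = 8L)
  expect_equal(tab$mse, unname(direct$mean_mse), tolerance = 1e-10)
  expect_identical(tab$drug_id, direct$drug_ids)
})
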