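test_that("svd_shrink handles diagonal, identity and random cases", {
  M <- diag(c(3, 1))
  expect_equal(svd_shrink(M, 2), diag(c(1, 0)))

  set.seed(7)
  A <- matrix(rnorm(24), 6, 4)
  expect_equal(svd_shrink(A, 0), A)

  out <- svd_shrink(A, 0.5)
  expect_equal(svd(out)$d, pmax(svd(A)$d - 0.5, 0), tolerance = 1e-10)

  expect_error(svd_shrink(matrix(c(1, NA), 1, 2), 1), "finite")
  expect_error(svd_shrink(A, -1), "non-negative")
})

test_that("w_update solves the ridge-augmented per-task problem exactly", {
  set.seed(11)
  N <- 25L; P <- 8L
  Xv <- matrix(rnorm(N * P), N, P)
  y <- rnorm(N)
  designs <- admm_designs(Xv, matrix(y, ncol = 1), standardize = FALSE)

  # large rho pins w at Z = 0, b at the response mean
  st <- admm_state(P, 1L, rho = 1e8)
  st <- admm_w_update(st, designs)
  expect_lt(max(abs(st$W)), 1e-4)
  expect_equal(st$b, mean(y), tolerance = 1e-4)

  # rho = 2, Z = Gamma = 0: minimizer of ||y - Xw - b||^2 + ||w||^2,
  # i.e. ridge with unit slope penalty and free intercept
  st <- admm_state(P, 1L, rho = 2)
  st <- admm_w_update(st, designs)
  Xc <- scale(Xv, scale = FALSE)
  yc <- y - mean(y)
  w_ref <- solve(crossprod(Xc) + diag(P), crossprod(Xc, yc))
  expect_equal(unname(st$W[, 1]), drop(w_ref), tolerance = 1e-10)
  expect_equal(st$b, mean(y) - sum(colMeans(Xv) * st$W[, 1]),
               tolerance = 1e-10)
})

test_that("w_update never increases the augmented Lagrangian", {
  aug_lagrangian <- function(st, designs, lambda) {
    s <- lambda * sum(svd(st$Z, nu = 0, nv = 0)$d) +
      sum(st$Gamma * (st$W - st$Z)) + st$rho / 2 * sum((st$W - st$Z)^2)
    for (t in seq_along(designs$tasks)) {
      tk <- designs$tasks[[t]]
      s <- s + sum((tk$y - tk$X %*% st$W[, t] - st$b[t])^2)
    }
    s
  }
  for (seed in 1:20) {
    set.seed(seed)
    dat <- random_instance(seed, N = 20L, P = 10L, T_ = 3L)
    designs <- admm_designs(dat$features, dat$responses,
                            standardize = FALSE)
    st <- admm_state(10L, 3L, rho = runif(1, 0.5, 4))
    st$W <- matrix(rnorm(30), 10, 3)
    st$b <- rnorm(3)
    st$Z <- matrix(rnorm(30), 10, 3)
    st$Gamma <- matrix(rnorm(30), 10, 3)
    before <- aug_lagrangian(st, designs, lambda = 1)
    after <- aug_lagrangian(admm_w_update(st, designs), designs,
                            lambda = 1)
    expect_lte(after, before + 1e-10)
  }
})

test_that("z_update is the trace-norm proximal map", {
  set.seed(5)
  st <- admm_state(5L, 3L, rho = 1.7)
  st$W <- matrix(rnorm(15), 5, 3)
  st$Gamma <- matrix(rnorm(15), 5, 3)

  # lambda = 0 passes W + Gamma/rho through unchanged
  out <- admm_z_update(st, 0)
  expect_equal(out$Z, st$W + st$Gamma / st$rho)

  # full shrinkage zeroes Z
  M <- st$W + st$Gamma / st$rho
  big <- max(svd(M)$d) * st$rho * 1.01
  expect_equal(admm_z_update(st, big)$Z, matrix(0, 5, 3))

  # proximal optimality versus random perturbations
  lambda <- 1.3
  st <- admm_z_update(st, lambda)
  prox_obj <- function(Z) {
    lambda * sum(svd(Z, nu = 0, nv = 0)$d) +
      st$rho / 2 * sum((Z - M)^2)
  }
  base <- prox_obj(st$Z)
  for (i in 1:1000) {
    expect_gte(prox_obj(st$Z + matrix(rnorm(15, sd = 0.1), 5, 3)),
               base - 1e-10)
  }
})

test_that("dual update is additive gradient ascent", {
  st <- admm_state(4L, 2L, rho = 1)
  st$W <- st$Z <- matrix(1, 4, 2)
  expect_equal(admm_dual_update(st)$Gamma, matrix(0, 4, 2))

  E <- matrix(rnorm(8), 4, 2)
  st$W <- st$Z + E
  expect_equal(admm_dual_update(st)$Gamma, E)
  twice <- admm_dual_update(admm_dual_update(st))
  expect_equal(twice$Gamma, 2 * E)
})

test_that("lambda = 0 fit recovers per-task ordinary least squares", {
  dat <- random_instance(3, N = 30L, P = 10L, T_ = 4L)
  m <- fit_trace_norm(dat$features, dat$responses, lambda = 0,
                      standardize = FALSE, tol_abs = 1e-7, tol_rel = 1e-6,
                      max_iter = 5000L)
  Xv <- dat$features$values
  for (t in 1:4) {
    ols <- lm(dat$responses$values[, t] ~ Xv)
    expect_equal(unname(m$W[, t]), unname(coef(ols)[-1]),
                 tolerance = 1e-5)
    expect_equal(unname(m$b[t]), unname(coef(ols)[1]), tolerance = 1e-5)
  }
})

test_that("a penalty above lambda_max collapses W to zero exactly", {
  dat <- random_instance(4, N = 30L, P = 12L, T_ = 4L)
  lmax <- lambda_max_trace_norm(dat$features, dat$responses,
                                standardize = FALSE)
  # subgradient check: zero is stationary iff the gradient matrix at
  # W = 0 has spectral norm <= lambda
  G <- vapply(1:4, function(t) {
    y <- dat$responses$values[, t]
    Xc <- scale(dat$features$values, scale = FALSE)
    2 * drop(crossprod(Xc, y - mean(y)))
  }, numeric(12L))
  expect_equal(lmax, max(svd(G)$d), tolerance = 1e-10)

  m <- fit_trace_norm(dat$features, dat$responses, lambda = 2 * lmax,
                      standardize = FALSE)
  expect_equal(unname(m$W), matrix(0, 12, 4))
  expect_equal(unname(m$b), unname(colMeans(dat$responses$values)))
  expect_equal(m$rank, 0L)
})

test_that("masked response entries never influence the fit", {
  dat <- random_instance(9, N = 40L, P = 15L, T_ = 5L)
  held <- holdout_mask(dat$responses, 0.25, "transductive", seed = 2)
  m1 <- fit_trace_norm(dat$features, held, lambda = 3)

  poisoned <- held$values
  poisoned[!held$mask] <- 1e6  # junk in the masked cells
  Y2 <- response_matrix(ifelse(held$mask, held$values, 1e6), held$mask,
                        held$cell_line_ids, held$drug_ids)
  m2 <- fit_trace_norm(dat$features, Y2, lambda = 3)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$b, m2$b)
})

test_that("warm-started paths match single fits and save iterations", {
  dat <- random_instance(5, N = 40L, P = 20L, T_ = 5L)
  lmax <- lambda_max_trace_norm(dat$features, dat$responses)
  grid <- trace_lambda_grid(lmax, 8L)

  single <- fit_trace_norm(dat$features, dat$responses, grid[1])
  path1 <- fit_trace_norm_path(dat$features, dat$responses,
                               lambdas = grid[1])
  expect_equal(path1[[1]]$W, single$W, tolerance = 1e-8)

  warm <- fit_trace_norm_path(dat$features, dat$responses, lambdas = grid)
  cold_iters <- sum(vapply(grid, function(l) {
    fit_trace_norm(dat$features, dat$responses, l)$n_iter
  }, numeric(1)))
  warm_iters <- sum(vapply(warm, `[[`, numeric(1), "n_iter"))
  expect_lte(warm_iters, cold_iters)

  # every path iterate beats the all-zero model at its own lambda
  zero_obj <- vapply(seq_along(grid), function(i) {
    d <- admm_designs(dat$features, dat$responses)
    s <- 0
    for (t in seq_along(d$tasks)) {
      s <- s + sum((d$tasks[[t]]$y - mean(d$tasks[[t]]$y))^2)
    }
    s
  }, numeric(1))
  expect_true(all(vapply(warm, `[[`, numeric(1), "objective") <=
                    zero_obj + 1e-8))

  expect_error(fit_trace_norm_path(dat$features, dat$responses,
                                   lambdas = c(1, 2)),
               "strictly decreasing")
})

test_that("numerical rank of W is non-increasing in lambda on average", {
  ranks <- matrix(NA_real_, 10, 10)
  for (s in 1:10) {
    dat <- random_instance(100 + s, N = 35L, P = 15L, T_ = 6L, rank = 3L)
    lmax <- lambda_max_trace_norm(dat$features, dat$responses)
    grid <- trace_lambda_grid(lmax, 10L)
    path <- fit_trace_norm_path(dat$features, dat$responses,
                                lambdas = grid)
    ranks[s, ] <- vapply(path, `[[`, numeric(1), "rank")
  }
  mean_rank <- colMeans(ranks)  # columns ordered by decreasing lambda
  expect_true(all(diff(mean_rank) >= -1e-9))
})

test_that("W and Z agree tightly at convergence", {
  dat <- random_instance(6, N = 40L, P = 20L, T_ = 5L)
  m <- fit_trace_norm(dat$features, dat$responses, lambda = 5,
                      tol_abs = 1e-6, tol_rel = 1e-5)
  st <- m$state
  expect_lte(sqrt(sum((st$W - st$Z)^2)) / sqrt(sum(st$Z^2)), 1e-3)
})
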