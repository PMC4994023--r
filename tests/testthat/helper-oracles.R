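# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals.

# Accelerated proximal-gradient (FISTA) minimizer of
#   sum_t ||y_t - X_t w_t - b_t||^2 + lambda ||W||_*
# run to tight tolerance; slow but independent of the ADMM path.
prox_gradient_ref <- function(Xv, Yv, mask, lambda, max_iter = 40000L,
                              tol = 1e-12) {
  P <- ncol(Xv)
  T_ <- ncol(Yv)
  tasks <- lapply(seq_len(T_), function(t) {
    idx <- which(mask[, t])
    list(X = Xv[idx, , drop = FALSE], y = Yv[idx, t])
  })
  L <- 2 * max(vapply(tasks, function(tk) svd(tk$X, nu = 0, nv = 0)$d[1]^2,
                      numeric(1))) + 2
  objective <- function(W, b) {
    s <- 0
    for (t in seq_len(T_)) {
      s <- s + sum((tasks[[t]]$y - tasks[[t]]$X %*% W[, t] - b[t])^2)
    }
    s + lambda * sum(svd(W, nu = 0, nv = 0)$d)
  }
  W <- matrix(0, P, T_)
  b <- vapply(tasks, function(tk) mean(tk$y), numeric(1))
  Wm <- W; bm <- b; th <- 1; old <- Inf
  for (k in seq_len(max_iter)) {
    G <- matrix(0, P, T_); gb <- numeric(T_)
    for (t in seq_len(T_)) {
      r <- drop(tasks[[t]]$X %*% Wm[, t]) + bm[t] - tasks[[t]]$y
      G[, t] <- 2 * crossprod(tasks[[t]]$X, r)
      gb[t] <- 2 * sum(r)
    }
    sv <- svd(Wm - G / L)
    d <- pmax(sv$d - lambda / L, 0)
    Wn <- sv$u %*% (d * t(sv$v))
    bn <- bm - gb / L
    thn <- (1 + sqrt(1 + 4 * th^2)) / 2
    Wm <- Wn + (th - 1) / thn * (Wn - W)
    bm <- bn + (th - 1) / thn * (bn - b)
    W <- Wn; b <- bn; th <- thn
    if (k %% 200L == 0L) {
      o <- objective(W, b)
      if (abs(old - o) < tol * max(1, o)) break
      old <- o
    }
  }
  list(W = W, b = b, objective = objective(W, b))
}

# Adjusted Rand index by explicit enumeration of all item pairs.
ari_pair_counting <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(same_a & same_b)
  n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b)
  n01 <- sum(!same_a & same_b)
  total <- choose(n, 2)
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == expected) return(0)
  (n11 - expected) / (max_index - expected)
}

# All set partitions of 1..n as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (l in seq_len(next_max + 1L)) {
      recurse(c(labels, l), max(next_max, l))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Plain-R nearest-drug-neighbor reference: quadratic loops, no shortcuts.
nearest_drug_ref <- function(Yv, train_mask, d, cells, min_overlap = 3L) {
  T_ <- ncol(Yv)
  preds <- numeric(length(cells))
  for (ci in seq_along(cells)) {
    c_ <- cells[ci]
    best_j <- NA_integer_
    best_r <- -Inf
    for (j in seq_len(T_)) {
      if (j == d || !train_mask[c_, j]) next
      joint <- which(train_mask[, d] & train_mask[, j])
      if (length(joint) < min_overlap) next
      if (sd(Yv[joint, j]) == 0) next
      r <- suppressWarnings(cor(Yv[joint, d], Yv[joint, j]))
      if (is.na(r)) r <- 0
      if (r > best_r) {
        best_r <- r
        best_j <- j
      }
    }
    if (is.na(best_j)) {
      preds[ci] <- mean(Yv[train_mask[, d], d])
    } else {
      joint <- which(train_mask[, d] & train_mask[, best_j])
      fit <- lm(Yv[joint, d] ~ Yv[joint, best_j])
      preds[ci] <- coef(fit)[1] + coef(fit)[2] * Yv[c_, best_j]
    }
  }
  preds
}

# small dense instance shared by several solver tests
random_instance <- function(seed, N = 40L, P = 20L, T_ = 6L, rank = 2L,
                            noise_sd = 0.5) {
  generate_synthetic(synthetic_spec(N = N, P = P, T = T_, rank = rank,
                                    noise_sd = noise_sd, seed = seed))
}
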