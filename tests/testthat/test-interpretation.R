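test_that("clustering merges identical columns first", {
  W <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  cl <- cluster_drug_models(W)
  expect_equal(cl$tree$height[1], 0)
  first <- cl$tree$merge[1, ]
  expect_setequal(cl$tree$labels[-first], c("a", "b"))
  # topology ((a,b),c)
  labels2 <- flat_cut(cl, 2)
  expect_equal(labels2[["a"]], labels2[["b"]])
  expect_false(labels2[["a"]] == labels2[["c"]])

  expect_error(cluster_drug_models(cbind(c(1, NA))), "finite")
})

test_that("well-separated Gaussian columns are perfectly recovered", {
  for (s in 1:5) {
    set.seed(s)
    centers <- cbind(rep(0, 10), rep(20, 10))
    W <- sapply(rep(1:2, each = 4), function(g) {
      centers[, g] + rnorm(10, sd = 0.5)
    })
    colnames(W) <- sprintf("d%d", 1:8)
    labels <- flat_cut(cluster_drug_models(W), 2)
    expect_equal(adjusted_rand(labels, rep(1:2, each = 4)), 1)
  }
})

test_that("flat_cut respects k bounds and extremes", {
  set.seed(2)
  W <- matrix(rnorm(40), 5, 8, dimnames = list(NULL, sprintf("d%d", 1:8)))
  cl <- cluster_drug_models(W)
  expect_length(unique(flat_cut(cl, 1)), 1L)
  expect_length(unique(flat_cut(cl, 8)), 8L)
  expect_error(flat_cut(cl, 0), "between 1 and 8")
  expect_error(flat_cut(cl, 9), "between 1 and 8")
})

test_that("adjusted Rand matches brute-force pair counting everywhere", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(2, 2, 7, 7)), 1)
  expect_equal(adjusted_rand(1:4, rep(1, 4)), 0)
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               ari_pair_counting(c(1, 1, 2, 2), c(1, 2, 1, 2)))

  # exhaustive: every pair of partitions of 6 items
  parts <- all_partitions(6)
  for (i in seq_along(parts)) {
    for (j in seq(i, length(parts), by = 7)) {  # thinned sweep of pairs
      expect_equal(adjusted_rand(parts[[i]], parts[[j]]),
                   ari_pair_counting(parts[[i]], parts[[j]]),
                   tolerance = 1e-12)
    }
  }

  # symmetry and label-renaming invariance
  set.seed(10)
  a <- sample(1:3, 12, replace = TRUE)
  b <- sample(1:4, 12, replace = TRUE)
  expect_equal(adjusted_rand(a, b), adjusted_rand(b, a))
  expect_equal(adjusted_rand(a, b),
               adjusted_rand(letters[a], rev(LETTERS)[b]))
  expect_error(adjusted_rand(1:3, 1:4), "same items")
})

test_that("hypergeometric enrichment matches the exact distribution", {
  # set identical to the selection, background twice as large
  n <- 10L
  feats <- sprintf("g%d", 1:(2 * n))
  w <- setNames(c(seq(2, 1.1, length.out = n), rep(0.01, n)), feats)
  gs <- gene_set_collection(list(hit = feats[1:n]), background = feats)
  res <- top_feature_enrichment(w, gs, n_top = n)
  expect_equal(res$p_value, dhyper(n, n, n, n), tolerance = 1e-12)

  # disjoint set: k = 0, small K, large M -> p well above 0.5
  gs2 <- gene_set_collection(list(miss = feats[(n + 1):(n + 3)]),
                             background = feats)
  res2 <- top_feature_enrichment(w, gs2, n_top = 5L)
  expect_equal(res2$overlap, 0L)
  expect_gt(res2$p_value, 0.5)

  # fully selected set inside a large background
  M <- 5000L
  bigbg <- sprintf("g%d", 1:M)
  wbig <- setNames(c(rep(1, 100), rep(0, M - 100)), bigbg)
  gs3 <- gene_set_collection(list(s = bigbg[1:10]), background = bigbg)
  res3 <- top_feature_enrichment(wbig, gs3, n_top = 100L)
  expect_lt(res3$p_value, 1e-6)

  # 100 random configurations against direct pmf summation
  set.seed(17)
  for (i in 1:100) {
    M <- sample(50:200, 1)
    K <- sample(5:30, 1)
    ntop <- sample(5:40, 1)
    bg <- sprintf("f%d", 1:M)
    w <- setNames(rnorm(M), bg)
    members <- sample(bg, K)
    gs <- gene_set_collection(list(s = members), background = bg)
    res <- top_feature_enrichment(w, gs, n_top = ntop)
    sel <- names(sort(abs(w), decreasing = TRUE))[1:ntop]
    k <- length(intersect(sel, members))
    p_ref <- sum(dhyper(k:min(K, ntop), K, M - K, ntop))
    expect_equal(res$p_value, p_ref, tolerance = 1e-10)
  }
})

test_that("positive mode falls back to all positive weights when sparse", {
  w <- setNames(c(3, 2, 1, -5, -4, 0), sprintf("g%d", 1:6))
  gs <- gene_set_collection(list(s = c("g1", "g2")),
                            background = names(w))
  res <- top_feature_enrichment(w, gs, n_top = 100L, mode = "positive")
  expect_equal(res$selected, 3L)  # only three positive weights exist
  expect_equal(res$overlap, 2L)

  w_neg <- setNames(c(-1, -2), c("g1", "g2"))
  gs2 <- gene_set_collection(list(s = "g1"), background = names(w_neg))
  expect_error(top_feature_enrichment(w_neg, gs2, mode = "positive"),
               "no positive-weight")
})
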