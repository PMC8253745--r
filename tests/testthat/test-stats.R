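test_that("identical conditions give no significant clusters", {
  set.seed(1)
  A <- lapply(1:6, function(i) matrix(rnorm(60), 10, 6))
  res <- cluster_permutation_test(A, A, n_perm = 200, seed = 1)
  expect_equal(nrow(res$clusters), 0)
  expect_true(all(res$t_map == 0))
})

test_that("cluster results are reproducible and bounded below by 1/(B+1)", {
  set.seed(2)
  A <- lapply(1:8, function(i) matrix(rnorm(80), 10, 8))
  B <- lapply(1:8, function(i) matrix(rnorm(80), 10, 8) + 0.5)
  r1 <- cluster_permutation_test(A, B, n_perm = 300, seed = 42)
  r2 <- cluster_permutation_test(A, B, n_perm = 300, seed = 42)
  expect_identical(r1$clusters, r2$clusters)
  expect_true(all(r1$clusters$p >= 1 / 301))
  expect_true(all(r1$clusters$p <= 1))
  expect_error(cluster_permutation_test(A[1], B[1], 100), "2 subjects")
  expect_error(cluster_permutation_test(A, lapply(B, t), 100), "grids")
})

test_that("swapping conditions flips cluster signs, keeps masses and p", {
  set.seed(3)
  A <- lapply(1:7, function(i) matrix(rnorm(60), 6, 10))
  B <- lapply(1:7, function(i) matrix(rnorm(60), 6, 10) + 0.8)
  ab <- cluster_permutation_test(A, B, n_perm = 400, seed = 5)
  ba <- cluster_permutation_test(B, A, n_perm = 400, seed = 5)
  expect_equal(sort(ab$clusters$mass), sort(-ba$clusters$mass))
  expect_equal(sort(ab$clusters$p), sort(ba$clusters$p))
  expect_equal(ab$t_map, -ba$t_map)
})

test_that("clusters are maximal 4-connected components of the t-map", {
  tmap <- matrix(0, 5, 5)
  tmap[1:2, 1] <- 5          # one positive cluster of 2
  tmap[4:5, 4:5] <- -5       # one negative cluster of 4
  tmap[1, 3] <- 5            # isolated point (diagonal from nothing)
  lab <- vestigait:::label_clusters_cpp(tmap, 2)
  expect_equal(length(lab$mass), 3)
  expect_equal(sort(lab$mass), c(-20, 5, 10))
})

test_that("null permutation p-values are exchangeability-valid", {
  set.seed(4)
  pvals <- replicate(60, {
    A <- lapply(1:6, function(i) matrix(rnorm(48), 8, 6))
    B <- lapply(1:6, function(i) matrix(rnorm(48), 8, 6))
    res <- cluster_permutation_test(A, B, n_perm = 150,
                                    seed = sample.int(1e6, 1))
    if (nrow(res$clusters)) min(res$clusters$p) else 1
  })
  # stochastically >= uniform: the empirical CDF must not sit above uniform
  ks <- suppressWarnings(stats::ks.test(pvals, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("repeated-measures ANOVA matches the textbook sums of squares", {
  X <- matrix(c(5, 6, 7, 4, 6, 8, 6, 7, 9), nrow = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  res <- rm_anova_planned(X)
  # independent sums-of-squares oracle
  gm <- mean(X)
  ss_cond <- nrow(X) * sum((colMeans(X) - gm)^2)
  ss_subj <- ncol(X) * sum((rowMeans(X) - gm)^2)
  ss_tot <- sum((X - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F_oracle <- (ss_cond / (ncol(X) - 1)) /
    (ss_err / ((ncol(X) - 1) * (nrow(X) - 1)))
  expect_equal(res$F, F_oracle)
  expect_equal(res$df, c(2L, 4L))
  expect_equal(res$eta_squared, ss_cond / ss_tot)
  expect_equal(res$partial_eta_squared, ss_cond / (ss_cond + ss_err))
  # planned comparisons are paired t-tests against the first condition
  tt <- t.test(X[, "a"], X[, "b"], paired = TRUE)
  expect_equal(res$pairwise$t[1], unname(tt$statistic))
  expect_equal(res$pairwise$p[1], tt$p.value)
})

test_that("ANOVA handles zero effects and location shifts", {
  X0 <- matrix(rep(c(3, 5, 9), 4), nrow = 4, byrow = TRUE)
  X0 <- X0[, c(1, 1, 2, 3)] * 0 + matrix(rep(c(2, 2, 2, 2), 4), 4)
  res0 <- rm_anova_planned(X0, conditions = letters[1:4])
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  expect_true(all(res0$pairwise$p == 1))

  set.seed(6)
  X <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, letters[1:4]))
  r1 <- rm_anova_planned(X)
  r2 <- rm_anova_planned(X + 100)
  expect_equal(r1$F, r2$F)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$eta_squared, r2$eta_squared)
  expect_error(rm_anova_planned(rbind(X, NA)), "missing")
})
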