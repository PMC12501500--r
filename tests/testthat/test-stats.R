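test_that("Welch t matches the demographics worked example and t.test", {
  # age row: 62 +- 12 (n=42) vs 62 +- 16 (n=33): no difference at all
  wt <- welch_t(62, 12, 42, 62, 16, 33)
  expect_equal(wt$t, 0)
  expect_equal(wt$p, 1)
  expect_equal(bonferroni_adjust(wt$p, 7), 1)
  # raw-sample form agrees with stats::t.test
  set.seed(71)
  x <- rnorm(12, 1); y <- rnorm(9)
  wt2 <- welch_t(x, y)
  tt <- stats::t.test(x, y)
  expect_equal(wt2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(wt2$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(wt2$p, tt$p.value, tolerance = 1e-12)
  expect_equal(welch_t(x, x)$t, 0)
  # summary form against a hand computation
  wt3 <- welch_t(10, 2, 5, 7, 3, 4)
  se2 <- 4 / 5 + 9 / 4
  expect_equal(wt3$t, 3 / sqrt(se2))
  expect_equal(wt3$df, se2^2 / ((4 / 5)^2 / 4 + (9 / 4)^2 / 3))
})

test_that("chi-squared handles proportional and skewed tables", {
  expect_equal(chi_squared(matrix(c(10, 10, 10, 10), 2))$chisq, 0)
  expect_equal(chi_squared(matrix(c(10, 10, 10, 10), 2))$p, 1)
  got <- chi_squared(matrix(c(20, 10, 10, 20), 2))
  expect_equal(got$chisq, 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30))
  expect_equal(got$df, 1)
  expect_error(chi_squared(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("Pearson correlation matches the closed form", {
  expect_equal(pearson_corr(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_corr(1:10, -(1:10))$r, -1)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_corr(x, y)$r, r_hand, tolerance = 1e-12)
  expect_error(pearson_corr(rep(1, 5), 1:5), "constant")
})

test_that("Bonferroni multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_equal(bonferroni_adjust(0.004, 6), 0.024)
  expect_equal(bonferroni_adjust(c(0.01, 0.5), 3), c(0.03, 1))
})

test_that("cluster test finds a constructed contiguous effect", {
  set.seed(72)
  G <- 40
  A <- matrix(rnorm(12 * G), 12)
  B <- matrix(rnorm(12 * G), 12)
  B[, 11:30] <- B[, 11:30] + 2.5
  ct <- cluster_permutation_test(A, B, n_perm = 500, seed = 1)
  sig <- which(ct$clusters$p_value < 0.05)
  expect_gte(length(sig), 1)
  covered <- unique(unlist(ct$members[sig]))
  expect_gte(length(intersect(covered, 11:30)) / 20, 0.8)
  expect_lt(length(setdiff(covered, 8:33)) / G, 0.1)
})

test_that("2-D clusters respect orthogonal adjacency", {
  set.seed(73)
  dims <- c(8, 10)   # time x frequency
  A <- matrix(rnorm(10 * 80), 10)
  B <- matrix(rnorm(10 * 80), 10)
  block <- as.vector(outer(2:4, (3:5 - 1) * 8, `+`))   # rows 2-4, cols 3-5
  B[, block] <- B[, block] + 3
  ct <- cluster_permutation_test(A, B, n_perm = 300, grid_dims = dims, seed = 2)
  best <- which.max(abs(ct$clusters$mass))
  expect_lt(ct$clusters$p_value[best], 0.05)
  expect_gte(length(intersect(ct$members[[best]], block)) / 9, 0.8)
  # two diagonal-only islands must not merge
  m <- rep(FALSE, 9); m[c(1, 5)] <- TRUE   # (1,1) and (2,2) of a 3x3
  expect_equal(max(cmcbursts:::label_components(m, c(3, 3))), 2)
})

test_that("random permutation p agrees with exhaustive enumeration (cluster)", {
  set.seed(74)
  A <- matrix(rnorm(3 * 25), 3)
  B <- matrix(rnorm(3 * 25) + 1.2, 3)
  ex <- cluster_permutation_test(A, B, n_perm = 20, seed = 1)   # 20 combos
  expect_true(ex$exhaustive)
  rnd <- cluster_permutation_test(A, B, n_perm = 5000, seed = 3)
  skip_if(nrow(ex$clusters) == 0)
  expect_equal(ex$clusters$p_value[1], rnd$clusters$p_value[1],
               tolerance = 0.02)
})

test_that("max-t GLM agrees with exhaustive enumeration and permutation t", {
  set.seed(75)
  n <- 6
  y <- matrix(rnorm(n) + c(0, 0, 0, 1.5, 1.5, 1.5), ncol = 1)
  X <- cbind(1, c(0, 0, 0, 1, 1, 1))
  ex <- permutation_glm_maxt(y, X, c(0, 1), n_perm = 720, seed = 1)
  expect_true(attr(ex, "exhaustive"))
  rnd <- permutation_glm_maxt(y, X, c(0, 1), n_perm = 4000, seed = 2)
  expect_equal(ex$p_corrected, rnd$p_corrected, tolerance = 0.03)
  # single outcome, no confounds: corrected p equals a permutation-t p
  t_obs <- abs(welch_t(y[4:6, 1], y[1:3, 1])$t)
  combs <- utils::combn(6, 3)
  null_t <- apply(combs, 2, function(ix)
    abs(stats::t.test(y[ix, 1], y[-ix, 1], var.equal = TRUE)$statistic))
  p_enum <- mean(null_t >= t_obs - 1e-12)
  expect_equal(ex$p_corrected, p_enum, tolerance = 0.05)
})

test_that("max-t GLM flags only the outcome carrying the effect", {
  hits <- others <- c()
  for (s in 1:10) {
    set.seed(600 + s)
    n <- 30
    grp <- rep(0:1, each = 15)
    Y <- matrix(rnorm(n * 12), n)
    Y[, 5] <- Y[, 5] + grp * 2.5
    X <- cbind(1, grp, rnorm(n), rbinom(n, 1, 0.5))
    g <- permutation_glm_maxt(Y, X, c(0, 1, 0, 0), n_perm = 500, seed = s)
    hits <- c(hits, g$p_corrected[5] < 0.05)
    others <- c(others, all(g$p_corrected[-5] > 0.05))
  }
  expect_gte(mean(hits), 0.9)
  expect_gte(mean(others), 0.9)
})

test_that("Freedman-Lane keeps confounded designs calibrated", {
  set.seed(76)
  fp <- replicate(60, {
    n <- 24
    grp <- rep(0:1, each = 12)
    age <- rnorm(n) + grp        # confound correlated with group
    Y <- matrix(rnorm(n * 3) + age, n)   # outcome driven by confound only
    X <- cbind(1, grp, age)
    any(permutation_glm_maxt(Y, X, c(0, 1, 0), n_perm = 200,
                             seed = sample.int(1e6, 1))$p_corrected < 0.05)
  })
  expect_lt(mean(fp), 0.12)
})

test_that("max-t corrected p never decreases as outcomes are added", {
  set.seed(77)
  n <- 20
  grp <- rep(0:1, each = 10)
  Y <- matrix(rnorm(n * 6), n)
  X <- cbind(1, grp)
  p3 <- permutation_glm_maxt(Y[, 1:3], X, c(0, 1), n_perm = 400, seed = 9)
  p6 <- permutation_glm_maxt(Y, X, c(0, 1), n_perm = 400, seed = 9)
  expect_true(all(p6$p_corrected[1:3] >= p3$p_corrected - 1e-12))
})

test_that("permutation engines are exactly reproducible under a seed", {
  set.seed(78)
  A <- matrix(rnorm(8 * 30), 8); B <- matrix(rnorm(8 * 30), 8)
  c1 <- cluster_permutation_test(A, B, n_perm = 200, seed = 5)
  c2 <- cluster_permutation_test(A, B, n_perm = 200, seed = 5)
  expect_identical(c1$clusters, c2$clusters)
  Y <- matrix(rnorm(16 * 4), 16)
  X <- cbind(1, rep(0:1, each = 8))
  g1 <- permutation_glm_maxt(Y, X, c(0, 1), n_perm = 200, seed = 5)
  g2 <- permutation_glm_maxt(Y, X, c(0, 1), n_perm = 200, seed = 5)
  expect_identical(g1$p_corrected, g2$p_corrected)
})

test_that("degenerate inputs are rejected or neutralized", {
  A <- matrix(rnorm(6 * 10), 6); B <- matrix(rnorm(6 * 10), 6)
  expect_error(cluster_permutation_test(A, B, n_perm = 0), "n_perm")
  expect_error(cluster_permutation_test(A[1, , drop = FALSE], B), "2 subjects")
  A0 <- A; A0[, 3] <- 1; B0 <- B; B0[, 3] <- 1   # zero variance point
  ct <- cluster_permutation_test(A0, B0, n_perm = 50, seed = 1)
  expect_equal(ct$t_obs[3], 0)
  X <- cbind(1, rep(0:1, each = 6), rep(0:1, each = 6))   # collinear
  expect_error(permutation_glm_maxt(matrix(rnorm(12), 12), X, c(0, 1, 0)),
               "rank deficient")
})
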