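test_that("A-prime has correct endpoints, closed form and monotonicity", {
  expect_equal(aPrime(0.7, 0.7), 0.5)
  expect_equal(aPrime(0, 0), 0.5)
  expect_equal(aPrime(1, 1), 0.5)
  expect_equal(aPrime(1, 0), 1)
  expect_equal(aPrime(0, 1), 0)
  expect_equal(aPrime(0.8, 0.2), 0.875)
  # symmetric below-chance branch
  expect_equal(aPrime(0.2, 0.8), 1 - aPrime(0.8, 0.2))
  # monotone nondecreasing in H for fixed F; nonincreasing in F for fixed H
  grid <- seq(0, 1, by = 0.05)
  for (f in c(0, 0.25, 0.5, 0.9)) {
    expect_true(all(diff(aPrime(grid, f)) >= -1e-12))
  }
  for (h in c(0.1, 0.5, 0.75, 1)) {
    expect_true(all(diff(aPrime(h, grid)) <= 1e-12))
  }
  expect_error(aPrime(1.2, 0), "probability")
  expect_error(aPrime(0.5, -0.1), "probability")
})

test_that("Fisher transform is exact, odd and invertible", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.95, 0.95, by = 0.1)
  expect_equal(fisherZ(-r), -fisherZ(r))
  expect_equal(fisherZInv(fisherZ(r)), r, tolerance = 1e-12)
  expect_error(fisherZ(1), "clipping")
})

test_that("paired and one-sample t tests reproduce hand calculations", {
  x <- c(3, 5, 7)
  r0 <- oneSampleTTest(x - c(2, 3, 4))  # diffs 1, 2, 3
  expect_equal(r0$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r0$dof, 2)
  rp <- pairedTTest(x, c(2, 3, 4))
  expect_equal(rp$statistic, r0$statistic)
  expect_equal(rp$effect_size_d, mean(1:3) / sd(1:3))
  ry <- pairedTTest(x, x)
  expect_equal(ry$statistic, 0)
  expect_equal(ry$p, 1)
  expect_error(pairedTTest(x, x + 1), "degenerate")
  # affine shifts of both members leave the paired t unchanged
  sh <- pairedTTest(x * 2 + 10, c(2, 3, 4) * 2 + 10)
  expect_equal(sh$statistic, rp$statistic, tolerance = 1e-12)
})

test_that("paired t-test rejects at the nominal rate under the null", {
  set.seed(99)
  n <- 29
  reject <- vapply(1:10000, function(i) {
    d <- rnorm(n)
    tt <- abs(mean(d) / (sd(d) / sqrt(n)))
    tt > qt(0.975, n - 1)
  }, logical(1))
  # independent arithmetic above; cross-check a sample against the package
  d <- rnorm(n)
  expect_equal(oneSampleTTest(d)$statistic, mean(d) / (sd(d) / sqrt(n)))
  expect_gte(mean(reject), 0.045)
  expect_lte(mean(reject), 0.055)
})

test_that("2x2 repeated-measures ANOVA matches the squared paired t", {
  set.seed(3)
  n <- 20
  cm <- matrix(rnorm(n * 4, mean = rep(c(0, 0.4, 0.1, 0.6), each = n)),
               n, 4)  # columns A1B1 A1B2 A2B1 A2B2
  res <- rmAnova2x2(cm)
  # validity-style effect: paired t on B-collapsed means
  tA <- pairedTTest(rowMeans(cm[, 1:2]), rowMeans(cm[, 3:4]))
  tB <- pairedTTest(rowMeans(cm[, c(1, 3)]), rowMeans(cm[, c(2, 4)]))
  expect_equal(res$F[res$effect == "task"], tA$statistic^2,
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "validity"], tB$statistic^2,
               tolerance = 1e-8)
  expect_true(all(res$df1 == 1 & res$df2 == n - 1))
  expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
  # purely additive effects: interaction F vanishes relative to the mains
  set.seed(4)
  add <- cbind(0, 1, 2, 3)[rep(1, 6), ] + 0.3 * (1:6) +
    matrix(rnorm(24, sd = 0.01), 6, 4)
  res_add <- rmAnova2x2(add)
  expect_lt(res_add$F[3], 1e-3 * min(res_add$F[1:2]))
  expect_error(rmAnova2x2(cm[, 1:3]), "4 cells")
  cm_na <- cm; cm_na[1, 2] <- NA
  expect_error(rmAnova2x2(cm_na), "incomplete-design")
})

test_that("ANOVA F statistics are calibrated under a null", {
  set.seed(11)
  ps <- replicate(300, {
    res <- rmAnova2x2(matrix(rnorm(12 * 4), 12, 4))
    res$p
  })
  rate <- rowMeans(ps < 0.05)
  expect_true(all(rate >= 0.01 & rate <= 0.11))
})

test_that("skipped correlation is a no-op on clean data and flags planted outliers", {
  set.seed(5)
  n <- 29
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n, sd = 0.5)
  res <- skippedCorrelation(x, y)
  if (length(res$outliers) == 0) {
    expect_identical(res$r, cor(x, y))  # exact, not approximate
  }
  # identity input: perfect correlation, nothing flagged
  x2 <- seq(-1, 1, length.out = 20)
  res2 <- skippedCorrelation(x2, x2 + 0.001 * rnorm(20, sd = 1e-6))
  expect_equal(res2$r, 1, tolerance = 1e-6)
  expect_length(res2$outliers, 0)
  # planted gross outlier on an otherwise tight line
  set.seed(8)
  xs <- seq(1, 28) + rnorm(28, sd = 0.2)
  ys <- 0.8 * xs + rnorm(28, sd = 0.5)
  xp <- c(xs, 15)
  yp <- c(ys, -40)
  resp <- skippedCorrelation(xp, yp)
  expect_true(29 %in% resp$outliers)
  expect_false(any(seq_len(28) %in% resp$outliers))
  expect_equal(resp$r, cor(xs, ys))
  expect_error(skippedCorrelation(1:5, 1:5), "n >= 10")
})

test_that("adjusted correlation equals the textbook partial correlation", {
  # covariate orthogonal to both leaves the correlation unchanged
  set.seed(7)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  z <- rnorm(40)
  zo <- lm.fit(cbind(1, x, y), z)$residuals  # orthogonal covariate
  expect_equal(adjustedCorrelation(x, y, zo), cor(x, y), tolerance = 1e-10)
  # y identical to the covariate -> partial correlation ~ 0
  expect_lt(abs(adjustedCorrelation(x, y, y)), 1e-10)
  # hand 5-point example vs the closed form
  x5 <- c(1, 2, 3, 5, 8); y5 <- c(2, 1, 4, 6, 9); z5 <- c(1, 1, 2, 3, 5)
  rxy <- cor(x5, y5); rxz <- cor(x5, z5); ryz <- cor(y5, z5)
  expect_equal(adjustedCorrelation(x5, y5, z5),
               (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
               tolerance = 1e-12)
  expect_warning(r <- adjustedCorrelation(x, y, rep(1, 40)), "constant")
  expect_equal(r, cor(x, y))
})

test_that("sign-flip permutation attains its minimal p for a constant effect", {
  res <- signFlipPermutation(rep(0.5, 25), n_perm = 999, rng_seed = 1)
  expect_equal(res$p, 1 / 1000)
  expect_error(signFlipPermutation(rep(0.5, 3)), "5 participants")
  expect_error(signFlipPermutation(rep(0.5, 25), n_perm = 0), "n_perm")
})

test_that("sign-flip p-values are close to uniform under a symmetric null", {
  set.seed(21)
  ps <- vapply(1:200, function(i) {
    signFlipPermutation(rnorm(12), n_perm = 299, rng_seed = i)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
  expect_gte(mean(ps < 0.05), 0.01)
  expect_lte(mean(ps < 0.05), 0.12)
})

test_that("voxelwise FWE recovers a single planted strong voxel", {
  n <- 15; V <- 50
  hits <- 0; clean <- 0
  for (seed in 1:60) {
    set.seed(seed)
    X <- matrix(rnorm(n * V), n, V)
    X[, 7] <- X[, 7] + 1.5  # strong planted effect (d = 1.5)
    res <- signFlipPermutation(X, n_perm = 499, mode = "voxelwise_fwe",
                               rng_seed = seed)
    if (res$significant[7]) hits <- hits + 1
    if (!any(res$significant[-7])) clean <- clean + 1
  }
  expect_gte(hits, 57)   # planted voxel survives in >= 95% of seeds
  expect_gte(clean, 51)  # false positives controlled near the 5% FWE level
})
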