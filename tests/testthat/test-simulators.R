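test_that("error process matches its covariance at the grid", {
  grid <- seq(0, 1, length.out = 10)
  e <- error_process(10000, grid, "gaussian", seed = 51)
  expect_lt(abs(var(e[, 5]) - 0.3), 0.02)
  expect_lt(abs(cor(e[, 1], e[, 10]) - exp(-1)), 0.03)
  # full covariance converges to 0.3 exp(-|s-t|) in Frobenius norm
  gam <- 0.3 * exp(-abs(outer(grid, grid, "-")))
  expect_lt(norm(cov(e) - gam, "F") / norm(gam, "F"), 0.05)
})

test_that("t and skew-t scenarios have the stated tail and skew behaviour", {
  grid <- seq(0, 1, length.out = 8)
  et <- error_process(8000, grid, "t5", seed = 52)
  # heavier tails than Gaussian: realized variance is scale * df/(df-2)
  expect_lt(abs(var(et[, 4]) - 0.3 * 5 / 3), 0.1)
  es <- error_process(8000, grid, "skew_t5", seed = 53)
  skew <- mean(((es[, 4] - mean(es[, 4])) / sd(es[, 4]))^3)
  expect_gt(skew, 0.3)  # positive slant implies right skew at every t
})

test_that("label counts are exact and outlier recipes have the printed supports", {
  for (s in 1:5) {
    sim <- simulate_fd(1, n = 100, contamination = 0.05, seed = s)
    expect_identical(sum(sim$labels), 5L)
    # magnitude offsets: curve mean minus 4t trend lies in [5, 8] by magnitude
    trend <- 4 * sim$data$grid
    off <- rowMeans(sweep(sim$data$values[, , 1], 2, trend))
    expect_true(all(abs(off[sim$labels]) > 4 & abs(off[sim$labels]) < 9))
    expect_true(all(abs(off[!sim$labels]) < 2.5))
  }
  sim0 <- simulate_fd(0, n = 200, contamination = 0.1, seed = 54)
  expect_identical(sum(sim0$labels), 20L)
  expect_true(all(sim0$outlier_kind[sim0$labels] == "isolated_shape"))
  expect_true(all(is.na(sim0$outlier_kind[!sim0$labels])))
  # c = 0: no outliers at all
  simc0 <- simulate_fd(4, n = 50, contamination = 0, seed = 55)
  expect_false(any(simc0$labels))
  # rounding half-up: 2.5 outliers -> 3
  expect_identical(sum(simulate_fd(1, n = 50, contamination = 0.05,
                                   seed = 56)$labels), 3L)
})

test_that("isolated shape perturbations live on short windows", {
  # compare each outlier to the same draw without contamination impossible;
  # instead check the perturbation support directly: difference from the
  # trend exceeds the noise scale on at most a few adjacent points
  sim <- simulate_fd(0, n = 100, contamination = 0.1, seed = 57)
  g <- sim$data$grid
  for (i in which(sim$labels)) {
    resid <- sim$data$values[i, , 1] - 4 * g
    big <- abs(resid) > 1.55   # 2 - noise is rarely below this
    expect_lte(sum(big), 4)
  }
})

test_that("mixed outliers split into the two printed types", {
  sim <- simulate_fd(9, n = 100, contamination = 0.1, seed = 58)
  kinds <- table(sim$outlier_kind[sim$labels])
  expect_identical(sort(names(kinds)), c("mixed_magnitude", "mixed_shape"))
  expect_identical(unname(kinds["mixed_magnitude"]), 5L)
  trend <- 4 * sim$data$grid
  off <- rowMeans(sweep(sim$data$values[, , 1], 2, trend))
  mag <- sim$outlier_kind == "mixed_magnitude" & !is.na(sim$outlier_kind)
  expect_true(all(off[mag] > -5.5 & off[mag] < -2.5))
})

test_that("matern correlation has its closed-form and limit properties", {
  expect_equal(matern(0, nu = 1.2, alpha = 0.02), 1)
  h <- seq(0.01, 2, length.out = 40)
  # nu = 1/2 reduces to the exponential correlation exp(-h / alpha)
  for (a in c(0.5, 1, 2)) {
    expect_all_equal(matern(h, nu = 0.5, alpha = a), exp(-h / a), tol = 1e-10)
  }
  # strictly decreasing in h for several smoothness values
  for (nu in c(0.6, 1, 1.2, 2.5)) {
    expect_true(all(diff(matern(h, nu = nu, alpha = 0.5)) < 0))
  }
  expect_error(matern(1, nu = -1, alpha = 1), "positive")
})

test_that("bivariate cross-covariance is valid and has the stated structure", {
  grid <- seq(0, 1, length.out = 50)
  sig <- aodetect:::bivariate_matern_cov(grid)
  expect_identical(dim(sig), c(100L, 100L))
  expect_equal(sig, t(sig))
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  # same-time cross-covariance is rho12 * sigma1 * sigma2 = 0.6
  expect_equal(unname(diag(sig[1:50, 51:100])), rep(0.6, 50))
  e <- aodetect:::rmvn_eigen(4000, sig)
  expect_lt(abs(cor(e[, 25], e[, 75]) - 0.6), 0.05)
  expect_lt(abs(var(e[, 25]) - 1), 0.08)
})

test_that("bivariate models contaminate as printed", {
  sim13 <- simulate_fd(13, n = 100, contamination = 0.1, seed = 59)
  expect_identical(sum(sim13$labels), 10L)
  m1 <- rowMeans(sim13$data$values[, , 1]); m2 <- rowMeans(sim13$data$values[, , 2])
  expect_gt(min(m1[sim13$labels]), max(0.4, quantile(m1[!sim13$labels], 0.9)))
  expect_gt(min(m2[sim13$labels]), 0.4)  # +1.2 shift in both components
  sim14 <- simulate_fd(14, n = 100, contamination = 0.1, seed = 60)
  s1 <- apply(sim14$data$values[, , 1], 1, sd)
  expect_gt(mean(s1[sim14$labels]) / mean(s1[!sim14$labels]), 1.3)
  sim15 <- simulate_fd(15, n = 100, contamination = 0.1, seed = 61)
  # amplitude of the cos component: U in [2,3] nominal vs [4,5] anomalous
  amp <- apply(sim15$data$values[, , 1], 1, function(r) diff(range(r))) / 2
  expect_gt(min(amp[sim15$labels]), max(3.2, quantile(amp[!sim15$labels], 0.8)))
  sim12 <- simulate_fd(12, n = 100, contamination = 0.1, seed = 62)
  # multiplicative +/-5 spikes create large local excursions
  mx <- apply(abs(sim12$data$values[, , 1]), 1, max)
  expect_gt(median(mx[sim12$labels]), median(mx[!sim12$labels]) * 2)
})

test_that("simulators are deterministic under seed", {
  a <- simulate_fd(8, n = 30, contamination = 0.1, seed = 63)
  b <- simulate_fd(8, n = 30, contamination = 0.1, seed = 63)
  expect_identical(a$data$values, b$data$values)
  expect_identical(a$labels, b$labels)
  c2 <- simulate_fd(12, n = 30, seed = 64)
  d2 <- simulate_fd(12, n = 30, seed = 64)
  expect_identical(c2$data$values, d2$data$values)
  expect_error(simulate_fd(16), "unknown model")
})
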