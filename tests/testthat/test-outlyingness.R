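test_that("directional outlyingness reduces to the signed scalar for p = 1", {
  x <- functional_data(matrix(c(1, 2, 3, 4, 100), 5, 3), grid = c(0, 0.5, 1))
  O <- directional_outlyingness(x)
  expect_equal(O$values[5, 1, 1], 97)   # (100 - 3) / 1
  expect_equal(O$values[1, 1, 1], -2)   # sign retained below the median
  # sign matches side of the pointwise median everywhere
  med <- apply(x$values[, , 1], 2, median)
  off <- sweep(x$values[, , 1], 2, med)
  expect_true(all(sign(O$values[, , 1])[off != 0] == sign(off)[off != 0]))
})

test_that("multivariate outlyingness recomposes norm times spatial sign", {
  # one point with equal unit scales: O = ||o|| * v must recompose o
  vals <- array(0, c(3, 3, 2))
  vals[1, , ] <- c(3, 3, 3, 4, 4, 4)       # curve of interest
  vals[2, , ] <- 0; vals[3, , ] <- 0       # push medians to 0
  x <- functional_data(vals, grid = c(0, 0.5, 1))
  s <- structure(list(location = matrix(0, 3, 2),
                      scale = matrix(1, 3, 2), kind = "median_mad",
                      grid = x$grid), class = "fd_summary")
  O <- directional_outlyingness(x, summary = s)
  expect_equal(unname(O$values[1, 1, ]), c(3, 4))  # ||o|| = 5, v = (0.6, 0.8)
  expect_equal(unname(O$values[2, 1, ]), c(0, 0))  # at the median: zero
})

test_that("curve at the pointwise median has zero outlyingness", {
  x <- toy_fd(n = 11, k = 9, seed = 5)   # odd n: the median curve exists
  med <- apply(x$values[, , 1], 2, median)
  v2 <- x$values; v2[1, , 1] <- med
  O <- directional_outlyingness(functional_data(v2, grid = x$grid))
  expect_equal(max(abs(O$values[1, , 1])), 0)
})

test_that("p = 1 outlyingness is odd under reflection about the median", {
  x <- toy_fd(n = 12, k = 10, seed = 6)
  med <- apply(x$values[, , 1], 2, median)
  refl <- functional_data(sweep(-x$values[, , 1], 2, 2 * med, "+"),
                          grid = x$grid)
  O1 <- directional_outlyingness(x)
  O2 <- directional_outlyingness(refl)
  expect_all_equal(O2$values, -O1$values, tol = 1e-9)
})

test_that("amo matches hand trapezoids and is linear in O", {
  g <- c(0, 1)
  w <- structure(list(values = matrix(c(0.5, 1.5), 2, 1), source = "w1",
                      grid = g), class = "fd_weight")
  O <- as_dirout_fixture(matrix(c(-1, 1), 1, 2), g)
  expect_equal(unname(amo(O, w)[1, 1]), 0.5)  # trapezoid of (-0.5, 1.5)
  Oz <- as_dirout_fixture(matrix(0, 1, 2), g)
  expect_equal(unname(amo(Oz, w)[1, 1]), 0)
  # linearity
  O2 <- as_dirout_fixture(matrix(c(2, -3), 1, 2), g)
  Osum <- as_dirout_fixture(rbind(O$values[1, , 1] + 2 * O2$values[1, , 1]), g)
  expect_equal(amo(Osum, w), amo(O, w) + 2 * amo(O2, w),
               ignore_attr = TRUE)
})

test_that("avo matches hand values, is nonnegative and shift invariant", {
  g <- c(0, 1)
  wu <- structure(list(values = matrix(1, 2, 1), source = "uniform",
                       grid = g), class = "fd_weight")
  O <- as_dirout_fixture(matrix(c(0, 2), 1, 2), g)
  expect_equal(avo(O, wu), 1)             # AMO = 1, trapezoid of (1, 1)
  Oc <- as_dirout_fixture(matrix(3, 1, 2), g)
  expect_equal(avo(Oc, wu), 0)            # constant O: no dispersion
  set.seed(7)
  Or <- as_dirout_fixture(matrix(rnorm(40), 4, 10), seq(0, 1, length.out = 10))
  wr <- structure(list(values = matrix(runif(10), 10, 1), source = "w2",
                       grid = Or$grid), class = "fd_weight")
  wr$values <- wr$values / grid_integrate(wr$values[, 1], Or$grid)
  expect_true(all(avo(Or, wr) >= 0))
  Oshift <- as_dirout_fixture(Or$values[, , 1] + 5, Or$grid)
  expect_all_equal(avo(Oshift, wr), avo(Or, wr), tol = 1e-10)
  # mismatched weight provenance is a configuration error
  a_w2 <- amo(Or, wr)
  wu10 <- structure(list(values = matrix(1, 10, 1), source = "uniform",
                         grid = Or$grid), class = "fd_weight")
  expect_error(avo(Or, wu10, a_w2), "same weight")
})

test_that("so matches the frozen hand-trapezoid oracle and flips sign", {
  g <- c(0, 0.5, 1)
  O <- as_dirout_fixture(matrix(c(0, 0, 3), 1, 3), g)
  # variance-normalised form: MO = 0.75, VO = 1.6875, SO = 0.52675...
  expect_equal(so(O, normalization = "variance"), 0.5267490, tolerance = 1e-6)
  # symmetric O about its mean integrates to zero
  Os <- as_dirout_fixture(matrix(c(-1, 1), 1, 2), c(0, 1))
  expect_equal(so(Os, normalization = "variance"), 0)
  expect_equal(so(Os, normalization = "sd"), 0)
  # mirrored curves flip the sign of the skewness, both normalisations
  for (nrm in c("sd", "variance")) {
    Om <- as_dirout_fixture(-O$values[, , 1, drop = FALSE], g)
    expect_equal(so(Om, normalization = nrm), -so(O, normalization = nrm))
  }
  # degenerate constant outlyingness contributes zero
  Oc <- as_dirout_fixture(matrix(2, 1, 3), g)
  expect_equal(so(Oc), 0)
})

test_that("uniform weights reduce AMO/AVO to unweighted MO/VO", {
  x <- toy_fd(n = 25, k = 16, seed = 8)
  O <- directional_outlyingness(x)
  wu <- fd_weight(x, "uniform")
  lambda <- diff(range(x$grid))
  # independently coded unweighted MO and VO
  mo_ref <- grid_integrate(O$values[, , 1], x$grid) / lambda
  vo_ref <- grid_integrate((O$values[, , 1] - mo_ref)^2, x$grid) / lambda
  expect_all_equal(drop(amo(O, wu)), mo_ref, tol = 1e-12)
  expect_all_equal(avo(O, wu), vo_ref, tol = 1e-12)
})

test_that("ao_matrix assembles p + 2 columns with expected structure", {
  sim <- simulate_fd(0, n = 80, contamination = 0.1, seed = 11)
  ao <- ao_matrix(sim$data)
  expect_identical(colnames(ao), c("AMO_1", "AVO", "SO"))
  expect_true(all(ao[, "AVO"] >= 0))
  expect_true(all(is.finite(ao)))
  # deterministic given the data
  expect_identical(ao, ao_matrix(sim$data))
  # anomalous curves separate from the nominal cloud in (AVO, SO)
  d_out <- mahalanobis(ao[, c("AVO", "SO")],
                       colMeans(ao[!sim$labels, c("AVO", "SO")]),
                       cov(ao[!sim$labels, c("AVO", "SO")]))
  expect_gt(median(d_out[sim$labels]), quantile(d_out[!sim$labels], 0.75))
  # all-identical curves propagate the degenerate-data error
  cst <- functional_data(matrix(1, 10, 8))
  expect_error(ao_matrix(cst), "degenerate")
  # bivariate data: p + 2 = 4 columns
  simb <- simulate_fd(13, n = 40, seed = 12)
  expect_identical(ncol(ao_matrix(simb$data)), 4L)
})

test_that("uniform-weight configuration reproduces unweighted moments end to end", {
  x <- toy_fd(n = 30, k = 14, seed = 13)
  ao <- ao_matrix(x, amo_weight = "uniform", avo_weight = "uniform")
  O <- directional_outlyingness(x)
  lambda <- diff(range(x$grid))
  mo_ref <- grid_integrate(O$values[, , 1], x$grid) / lambda
  vo_ref <- grid_integrate((O$values[, , 1] - mo_ref)^2, x$grid) / lambda
  expect_all_equal(ao[, "AMO_1"], mo_ref, tol = 1e-12)
  expect_all_equal(ao[, "AVO"], vo_ref, tol = 1e-12)
})

test_that("ao matrix CSV export roundtrips", {
  sim <- simulate_fd(1, n = 20, contamination = 0.1, seed = 14)
  ao <- ao_matrix(sim$data)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ao_csv(ao, f)
  back <- read.csv(f)
  expect_equal(back$AVO, unname(ao[, "AVO"]), tolerance = 1e-6)
  expect_identical(back$curve_id, rownames(ao))
})
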