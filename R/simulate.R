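# Simulators for the benchmark models: univariate models 0-11 (three
# error scenarios, four outlier types) and bivariate Matern models 12-15,
# all with ground-truth labels.

# exponential cross-sectional covariance gamma(s,t) = 0.3 exp(-|s-t|)
error_cov <- function(grid) 0.3 * exp(-abs(outer(grid, grid, "-")))

# multivariate skew-t draws (Azzalini-Capitanio construction): skew-normal
# via the conditioning representation, divided by sqrt(chisq_df / df)
rmst <- function(n, scale, df, slant) {
  k <- ncol(scale)
  omega <- sqrt(diag(scale))
  corr <- stats::cov2cor(scale)
  alpha <- rep(slant, length.out = k)
  delta <- drop(corr %*% alpha) / sqrt(1 + drop(crossprod(alpha, corr %*% alpha)))
  aug <- rbind(c(1, delta), cbind(delta, corr))
  z <- MASS::mvrnorm(n, rep(0, k + 1L), aug)
  sn <- z[, -1L, drop = FALSE] * sign(z[, 1L])      # multivariate skew-normal
  w <- stats::rchisq(n, df) / df
  sweep(sn / sqrt(w), 2L, omega, "*")
}

#' Error-process draws for the univariate models
#'
#' Draws `n` realisations of the noise process on `grid` under one of
#' three scenarios, all built on the exponential covariance
#' `gamma(s, t) = 0.3 exp(-|s - t|)`: `"gaussian"` is a mean-zero
#' multivariate normal with that covariance; `"t5"` a multivariate t with
#' 5 degrees of freedom and that scale matrix; `"skew_t5"` a multivariate
#' skew-t (Azzalini type) with 5 degrees of freedom, location 0 and slant
#' vector (2, ..., 2), giving right-skewed errors.  For the t scenarios
#' the exponential matrix is the *scale* matrix, not the realised
#' covariance (they differ by the factor df/(df-2)).
#'
#' @param n number of draws.
#' @param grid evaluation grid on `[0, 1]`.
#' @param scenario `"gaussian"`, `"t5"` or `"skew_t5"`.
#' @param seed optional integer seed.
#' @return `n x k` matrix of error curves.
#' @export
error_process <- function(n, grid, scenario = c("gaussian", "t5", "skew_t5"),
                          seed = NULL) {
  scenario <- match.arg(scenario)
  sig <- error_cov(grid)
  with_seed(seed, switch(scenario,
    gaussian = MASS::mvrnorm(n, rep(0, length(grid)), sig),
    t5 = MASS::mvrnorm(n, rep(0, length(grid)), sig) /
      sqrt(stats::rchisq(n, 5) / 5),
    skew_t5 = rmst(n, sig, df = 5, slant = 2)))
}

#' Matern correlation function
#'
#' `M(h; nu, alpha) = 2^(1 - nu) / Gamma(nu) * (h / alpha)^nu *
#' K_nu(h / alpha)` with `K_nu` the modified Bessel function of the second
#' kind, smoothness `nu > 0` and range `alpha > 0` (correlation decays
#' over distances comparable to `alpha`); `M(0) = 1` by the continuity
#' limit.  For `nu = 0.5` it reduces to the exponential correlation
#' `exp(-h / alpha)`.
#'
#' @param h nonnegative distances (vectorised).
#' @param nu smoothness parameter.
#' @param alpha range parameter.
#' @return Correlations in `[0, 1]`, strictly decreasing in `h`.
#' @examples
#' matern(0.5, nu = 0.5, alpha = 1)  # exp(-0.5)
#' @export
matern <- function(h, nu, alpha) {
  if (nu <= 0 || alpha <= 0) stop("nu and alpha must be positive", call. = FALSE)
  if (any(h < 0)) stop("distances must be nonnegative", call. = FALSE)
  x <- h / alpha
  out <- rep(1, length(h))
  pos <- h > 0
  val <- 2^(1 - nu) / gamma(nu) * x[pos]^nu * besselK(x[pos], nu)
  val[!is.finite(val)] <- 0  # Bessel underflow at large h
  out[pos] <- val
  dim(out) <- dim(h)
  out
}

default_matern_params <- function() {
  list(sigma = c(1, 1), rho12 = 0.6,
       alpha = matrix(c(0.02, 0.016, 0.016, 0.01), 2, 2),
       nu = matrix(c(1.2, 1, 1, 0.6), 2, 2))
}

# stacked 2k x 2k bivariate Matern cross-covariance on `grid`
bivariate_matern_cov <- function(grid, params = default_matern_params()) {
  h <- abs(outer(grid, grid, "-"))
  blk <- function(i, j) params$sigma[i] * params$sigma[j] *
    (if (i == j) 1 else params$rho12) *
    matern(h, params$nu[i, j], params$alpha[i, j])
  rbind(cbind(blk(1, 1), blk(1, 2)),
        cbind(blk(2, 1), blk(2, 2)))
}

# draws from N(0, sigma) via symmetric eigendecomposition with clipping of
# tiny negative eigenvalues (cross-covariance matrices are borderline PSD)
rmvn_eigen <- function(n, sigma, tol = 1e-8) {
  e <- eigen(sigma, symmetric = TRUE)
  lo <- min(e$values); hi <- max(e$values)
  if (lo < -tol * max(hi, 1))
    stop("covariance matrix is not positive semi-definite within tolerance",
         call. = FALSE)
  if (lo < 0)
    warning("clipping tiny negative covariance eigenvalues", call. = FALSE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(sigma))
  matrix(stats::rnorm(n * nrow(sigma)), n) %*% t(L)
}

round_half_up <- function(x) floor(x + 0.5)

model_scenario <- function(model) {
  switch(as.character(model),
         "0" = "gaussian", "1" = "gaussian", "2" = "t5", "3" = "skew_t5",
         "4" = "gaussian", "5" = "t5", "6" = "skew_t5",
         "7" = "t5", "8" = "skew_t5",
         "9" = "gaussian", "10" = "t5", "11" = "skew_t5",
         stop("unknown model id: ", model, call. = FALSE))
}

model_family <- function(model) {
  if (model %in% c(1, 2, 3)) "magnitude"
  else if (model %in% c(4, 5, 6)) "persistent_shape"
  else if (model %in% c(0, 7, 8)) "isolated_shape"
  else if (model %in% c(9, 10, 11)) "mixed"
  else "bivariate"
}

simulate_univariate <- function(model, n, k, contamination) {
  grid <- seq(0, 1, length.out = k)
  scenario <- model_scenario(model)
  family <- model_family(model)
  n_out <- round_half_up(contamination * n)
  labels <- rep(FALSE, n)
  out_idx <- if (n_out > 0) sample.int(n, n_out) else integer(0)
  labels[out_idx] <- TRUE
  level <- if (family == "magnitude") stats::runif(n, -1, 1) else numeric(n)
  vals <- matrix(rep(4 * grid, each = n), n, k) + level +
    error_process(n, grid, scenario)
  kind <- rep(NA_character_, n)
  if (n_out > 0) {
    if (family == "magnitude") {
      # outliers carry the level T, |T| ~ U(5, 8) with random sign,
      # instead of the nominal U(-1, 1) level
      T_ <- stats::runif(n_out, 5, 8) * sample(c(-1, 1), n_out, replace = TRUE)
      vals[out_idx, ] <- vals[out_idx, ] - level[out_idx] + T_
      kind[out_idx] <- "magnitude"
    } else if (family == "persistent_shape") {
      eta <- stats::runif(n_out, 0.25, 0.75)
      vals[out_idx, ] <- vals[out_idx, ] +
        1.5 * sin(outer(eta, 4 * pi * grid, "+"))
      kind[out_idx] <- "persistent_shape"
    } else if (family == "isolated_shape") {
      U <- sample(c(-1, 1), n_out, replace = TRUE)
      T_ <- stats::runif(n_out, 0, 0.8)
      win <- outer(T_, grid, function(a, t) t >= a & t <= a + 0.05)
      vals[out_idx, ] <- vals[out_idx, ] + 2 * U * win
      kind[out_idx] <- "isolated_shape"
    } else { # mixed: two anomaly types in equal proportions
      kinds <- sample(rep(c("mixed_magnitude", "mixed_shape"),
                          length.out = n_out))
      mag <- out_idx[kinds == "mixed_magnitude"]
      shp <- out_idx[kinds == "mixed_shape"]
      if (length(mag)) {
        T_ <- stats::runif(length(mag), -5, -3)
        vals[mag, ] <- vals[mag, ] + T_
      }
      if (length(shp)) {
        eta <- stats::runif(length(shp), 0.25, 0.75)
        vals[shp, ] <- vals[shp, ] + 1.5 * sin(outer(eta, 4 * pi * grid, "+"))
      }
      kind[mag] <- "mixed_magnitude"; kind[shp] <- "mixed_shape"
    }
  }
  list(values = vals, grid = grid, labels = labels, kind = kind,
       scenario = scenario, family = family)
}

simulate_bivariate <- function(model, n, k, contamination,
                               params = default_matern_params()) {
  grid <- seq(0, 1, length.out = k)
  sigma <- bivariate_matern_cov(grid, params)
  n_out <- round_half_up(contamination * n)
  labels <- rep(FALSE, n)
  out_idx <- if (n_out > 0) sample.int(n, n_out) else integer(0)
  labels[out_idx] <- TRUE
  e <- rmvn_eigen(n, sigma)
  e1 <- e[, seq_len(k), drop = FALSE]
  e2 <- e[, k + seq_len(k), drop = FALSE]
  kind <- rep(NA_character_, n)
  if (model == 12) {           # isolated multiplicative spike
    if (n_out > 0) {
      T_ <- stats::runif(n_out, 0, 0.9)
      sgn <- ifelse(T_ > 0.45, 5, -5)
      win <- outer(seq_len(n_out), grid,
                   function(i, t) t >= T_[i] & t <= T_[i] + 0.1)
      fac <- 1 + sgn * win
      e1[out_idx, ] <- e1[out_idx, ] * fac
      e2[out_idx, ] <- e2[out_idx, ] * fac
      kind[out_idx] <- "isolated"
    }
  } else if (model == 13) {    # shift in both components
    e1[out_idx, ] <- e1[out_idx, ] + 1.2
    e2[out_idx, ] <- e2[out_idx, ] + 1.2
    kind[out_idx] <- "shift"
  } else if (model == 14) {    # amplitude inflation
    e1[out_idx, ] <- 1.7 * e1[out_idx, ]
    e2[out_idx, ] <- 1.5 * e2[out_idx, ]
    kind[out_idx] <- "amplitude"
  } else if (model == 15) {    # deterministic shape with inflated amplitude
    u1 <- stats::runif(n, 2, 3); u2 <- stats::runif(n, 2, 3)
    u1[out_idx] <- stats::runif(n_out, 4, 5)
    u2[out_idx] <- stats::runif(n_out, 4, 5)
    e1 <- e1 + u1 %o% cos(4 * pi * grid)
    e2 <- e2 + u2 %o% sin(4 * pi * grid)
    kind[out_idx] <- "shape"
  } else stop("unknown bivariate model id: ", model, call. = FALSE)
  vals <- array(c(e1, e2), c(n, k, 2L))
  list(values = vals, grid = grid, labels = labels, kind = kind,
       scenario = "bivariate_matern", family = "bivariate")
}

#' Simulate the benchmark models with ground-truth labels
#'
#' Generates one labelled functional data set from the benchmark suite.
#' Univariate models (grid of `k` equidistant points on `[0, 1]`, error
#' process per [error_process()]):
#' \describe{
#'   \item{1-3}{magnitude outliers: normal curves `4t + U + e(t)` with
#'     `U ~ U(-1, 1)`; outliers `4t + T + e(t)` with `|T| ~ U(5, 8)` and a
#'     random sign.  Errors: Gaussian / t5 / skew-t5.}
#'   \item{4-6}{persistent shape outliers: normal `4t + e(t)`; outliers
#'     `4t + 1.5 sin(4 pi t + eta) + e(t)`, `eta ~ U(0.25, 0.75)`.}
#'   \item{0, 7, 8}{isolated shape outliers: normal `4t + e(t)`; outliers
#'     `4t + 2U I(T <= t <= T + 0.05) + e(t)` with `U = +/-1` equiprobable
#'     and `T ~ U(0, 0.8)`.  Model 0 is the Gaussian case.}
#'   \item{9-11}{mixed: half the outliers are level shifts with
#'     `T ~ U(-5, -3)`, half the sinusoidal shape anomaly.}
#' }
#' Bivariate models 12-15 draw `e(t) = (e1, e2)` from the mean-zero
#' bivariate Gaussian process with Matern cross-covariance
#' `C_ij(s, t) = rho_ij sigma_i sigma_j M(|s - t|; nu_ij, alpha_ij)`
#' (parameters `sigma1 = sigma2 = 1`, `alpha11 = 0.02`, `alpha22 = 0.01`,
#' `alpha12 = 0.016`, `nu11 = 1.2`, `nu22 = 0.6`, `nu12 = 1`,
#' `rho12 = 0.6`), then contaminate: model 12 multiplies by
#' `1 +/- 5 I(T <= t <= T + 0.1)` (sign + if `T > 0.45`); model 13 shifts
#' both components by +1.2; model 14 scales the components by 1.7 and 1.5;
#' model 15 adds `U cos(4 pi t)` / `U sin(4 pi t)` with `U ~ U(2, 3)` for
#' normal curves and `U ~ U(4, 5)` for outliers.
#'
#' The number of outliers is `round(contamination * n)` (half-up), their
#' positions drawn uniformly without replacement.
#'
#' @param model model id in `0:15`.
#' @param n number of curves.
#' @param k grid size; defaults to 30 (univariate) or 50 (bivariate).
#' @param contamination outlier proportion `c` in `[0, 1)`; default 0.05
#'   univariate, 0.1 bivariate.
#' @param seed optional integer seed; draws are deterministic given it.
#' @return Class `"fd_sim"`: list with `data` (an `"fdset"`), logical
#'   `labels` (`TRUE` = outlier), `outlier_kind`, `model`, `scenario` and
#'   the generating parameters.
#' @examples
#' sim <- simulate_fd(1, n = 100, contamination = 0.05, seed = 1)
#' sum(sim$labels)  # 5
#' @export
simulate_fd <- function(model, n = 100, k = NULL, contamination = NULL,
                        seed = NULL) {
  if (!model %in% 0:15) stop("unknown model id: ", model, call. = FALSE)
  bivariate <- model >= 12
  if (is.null(k)) k <- if (bivariate) 50L else 30L
  if (is.null(contamination)) contamination <- if (bivariate) 0.1 else 0.05
  if (contamination < 0 || contamination >= 1)
    stop("`contamination` must be in [0, 1)", call. = FALSE)
  res <- with_seed(seed, if (bivariate)
    simulate_bivariate(model, n, k, contamination)
  else simulate_univariate(model, n, k, contamination))
  data <- functional_data(res$values, grid = res$grid)
  structure(list(data = data, labels = res$labels,
                 outlier_kind = res$kind, model = model,
                 scenario = res$scenario, family = res$family,
                 n = n, k = k, contamination = contamination, seed = seed),
            class = "fd_sim")
}

#' @export
print.fd_sim <- function(x, ...) {
  cat(sprintf("Simulated model %d (%s, %s): n = %d, k = %d, %d outliers\n",
              x$model, x$family, x$scenario, x$n, x$k, sum(x$labels)))
  invisible(x)
}
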