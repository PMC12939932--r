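# Robust location/scatter estimation of the AO cloud and squared robust
# Mahalanobis distances.

# local seeding that restores the caller's RNG stream on exit
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic substream seeds drawn from the current stream
split_seeds <- function(n) sample.int(2147483646L, n)

new_robust_estimate <- function(location, scatter, method, meta) {
  dimnames(scatter) <- list(names(location), names(location))
  structure(list(location = location, scatter = scatter, method = method,
                 meta = meta),
            class = "robust_estimate")
}

#' @export
print.robust_estimate <- function(x, ...) {
  cat(sprintf("Robust estimate (%s), d = %d\n", x$method, length(x$location)))
  cat("location:", format(x$location, digits = 4), "\n")
  cat("log-det scatter:", format(determinant(x$scatter)$modulus[1], digits = 4), "\n")
  invisible(x)
}

# ridge-regularize a scatter matrix that is not numerically PD
ensure_pd <- function(sigma, context) {
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  d <- ncol(sigma)
  tol <- 1e-10 * max(abs(ev), 1)
  if (min(ev) <= tol) {
    ridge <- 1e-8 * max(sum(diag(sigma)) / d, 1e-12)
    sigma <- sigma + diag(ridge - min(min(ev), 0), d)
    warning(sprintf("singular scatter in %s; ridge-regularized", context),
            call. = FALSE)
  }
  sigma
}

# Gaussian consistency factor for an h/n-trimmed covariance: the raw
# covariance of the h most concentrated of n Gaussian points estimates
# c * Sigma with c = P(chisq_{d+2} <= q_{d,h/n}) / (h/n).
mcd_consistency <- function(h, n, d) {
  if (h >= n) return(1)
  alpha <- h / n
  alpha / stats::pchisq(stats::qchisq(alpha, d), d + 2)
}

# mean and covariance (n-1 denominator) of x[subset, ] without the
# dispatch overhead of stats::cov
subset_moments <- function(x, subset) {
  m <- x[subset, , drop = FALSE]
  mu <- colMeans(m)
  xc <- m - rep(mu, each = nrow(m))
  list(mu = mu, sig = crossprod(xc) / (nrow(m) - 1L))
}

# One concentration run: from `subset`, iterate C-steps (mean/cov on the
# subset, rank all points by Mahalanobis distance, keep the h closest)
# until the log-determinant stabilises or the covariance turns singular.
# Returns the final mean/cov and the logged determinant sequence, which is
# nonincreasing by construction.  Determinants and distances are computed
# from one Cholesky factor per iteration.
c_step_concentrate <- function(x, subset, max_iter = 100) {
  h <- length(subset)
  n <- nrow(x)
  mom <- subset_moments(x, subset)
  dets <- numeric(0)
  for (it in seq_len(max_iter)) {
    R <- tryCatch(chol(mom$sig), error = function(e) NULL)
    ld <- if (is.null(R)) -Inf else 2 * sum(log(diag(R)))
    dets <- c(dets, ld)
    if (!is.finite(ld)) break                        # singular: exact fit
    if (length(dets) > 1 && ld >= dets[length(dets) - 1L] - 1e-12) break
    if (h == n) break                                # full subset is a fixed point
    z <- backsolve(R, t(x) - mom$mu, transpose = TRUE)
    d2 <- colSums(z * z)
    cut <- sort(d2, partial = h)[h]
    subset <- which(d2 <= cut)
    if (length(subset) > h) subset <- subset[seq_len(h)]  # distance ties
    mom <- subset_moments(x, subset)
  }
  list(mu = mom$mu, sig = mom$sig, dets = dets, subset = subset)
}

#' Bootstrap minimum covariance determinant estimator
#'
#' Robust location and scatter of a point cloud (typically an AO matrix)
#' by repeated subsampling across several trimming proportions.  In each
#' of `B` rounds, one without-replacement subsample of size
#' `ceiling(c * n)` is drawn per proportion `c` and concentrated to its
#' determinant-minimising subset of that size by C-steps (see
#' [fast_mcd()]); the candidate with the smallest covariance determinant
#' wins the round (ties: the first, lowest-proportion candidate), which
#' adapts the effective trimming to the unknown outlier prevalence.  The
#' final estimate is the elementwise mean over the `B` round winners, each
#' candidate's scatter rescaled by the Gaussian consistency factor for its
#' subset size before averaging so distances on clean Gaussian data track
#' `chisq_d`.  `concentrate = FALSE` drops the C-steps and uses the raw
#' subsample mean/covariance per candidate (cheaper, far less robust).
#'
#' @param x numeric matrix (`n x d`), rows are observations.
#' @param percents subsample proportions in (0, 1].
#' @param B number of resampling rounds.
#' @param concentrate run C-steps on every candidate (default `TRUE`).
#' @param seed optional integer; the estimate is deterministic given it.
#' @return A `"robust_estimate"` with `location`, symmetric
#'   positive-definite `scatter` (ridge-regularized with a warning if
#'   needed), `method = "bootstrap_mcd"` and provenance metadata
#'   (including the per-round winning proportions).
#' @examples
#' z <- matrix(rnorm(300), 100, 3)
#' bootstrap_mcd(z, B = 20, seed = 1)
#' @export
bootstrap_mcd <- function(x, percents = c(0.85, 0.90, 0.95), B = 100,
                          concentrate = TRUE, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n <= d) stop("need more observations than dimensions", call. = FALSE)
  if (any(percents <= 0) || any(percents > 1))
    stop("`percents` must lie in (0, 1]", call. = FALSE)
  if (B < 1) stop("`B` must be >= 1", call. = FALSE)
  percents <- sort(percents)
  sizes <- ceiling(percents * n)
  if (min(sizes) <= d)
    stop("smallest subsample size must exceed the dimension", call. = FALSE)
  cfac <- vapply(sizes, mcd_consistency, 0, n = n, d = d)
  with_seed(seed, {
    mu_sum <- numeric(d)
    sig_sum <- matrix(0, d, d)
    winners <- integer(B)
    for (b in seq_len(B)) {
      best_ld <- Inf; best_mu <- NULL; best_sig <- NULL; best_j <- NA_integer_
      for (j in seq_along(sizes)) {
        idx <- sample.int(n, sizes[j])
        if (concentrate) {
          cand <- c_step_concentrate(x, idx)
          mu <- cand$mu
          sig <- cand$sig * cfac[j]  # consistency before averaging
          ld <- cand$dets[length(cand$dets)]
        } else {
          # raw subsample mean/covariance: unbiased, no rescaling
          mom <- subset_moments(x, idx)
          mu <- mom$mu; sig <- mom$sig
          dt <- determinant(sig, logarithm = TRUE)
          ld <- if (dt$sign <= 0) -Inf else as.numeric(dt$modulus)
        }
        if (ld < best_ld) {
          best_ld <- ld; best_mu <- mu; best_sig <- sig
          best_j <- j
        }
      }
      mu_sum <- mu_sum + best_mu
      sig_sum <- sig_sum + best_sig
      winners[b] <- best_j
    }
    location <- mu_sum / B
    scatter <- ensure_pd(sig_sum / B, "bootstrap_mcd")
    names(location) <- colnames(x)
    new_robust_estimate(location, scatter, "bootstrap_mcd",
                        list(percents = percents, B = B, seed = seed,
                             concentrate = concentrate,
                             consistency = if (concentrate) cfac else rep(1, length(sizes)),
                             winning_percents = percents[winners]))
  })
}

#' FAST-MCD robust location and scatter
#'
#' Concentration (C-step) algorithm: starting from a random `h`-subset,
#' iteratively estimate mean and covariance on the current subset, rank
#' all points by Mahalanobis distance and keep the `h` closest, until the
#' covariance determinant stabilises or becomes singular (its log-det
#' sequence is provably nonincreasing).  Several random starts are run and
#' the subset with the smallest determinant wins.  The raw scatter is
#' rescaled by the usual Gaussian consistency factor
#' `(h/n) / P(chisq_{d+2} <= q)` with `q` the `h/n` quantile of
#' `chisq_d`, so distances on clean Gaussian data track `chisq_d`.
#'
#' @param x numeric matrix (`n x d`).
#' @param h subset size, `d < h <= n`; default `floor(0.75 * n)`.
#' @param nstarts number of random starts.
#' @param max_iter cap on C-steps per start.
#' @param seed optional integer seed.
#' @return A `"robust_estimate"` with `method = "fast_mcd"`; its `meta`
#'   carries `h`, the winning start's log-determinant sequence
#'   (`det_sequence`) and all starts' sequences (`det_sequences`).
#' @export
fast_mcd <- function(x, h = NULL, nstarts = 5, max_iter = 100, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (is.null(h)) h <- max(floor(0.75 * n), d + 1L)
  if (h <= d || h > n) stop("need d < h <= n", call. = FALSE)
  with_seed(seed, {
    best <- list(logdet = Inf)
    sequences <- vector("list", nstarts)
    for (s in seq_len(nstarts)) {
      start <- if (h == n) seq_len(n) else sample.int(n, h)
      cand <- c_step_concentrate(x, start, max_iter)
      sequences[[s]] <- cand$dets
      final_ld <- cand$dets[length(cand$dets)]
      if (final_ld < best$logdet)
        best <- list(logdet = final_ld, mu = cand$mu, sig = cand$sig,
                     seq = cand$dets)
    }
    cfac <- mcd_consistency(h, n, d)
    scatter <- ensure_pd(best$sig * cfac, "fast_mcd")
    location <- best$mu
    names(location) <- colnames(x)
    new_robust_estimate(location, scatter, "fast_mcd",
                        list(h = h, nstarts = nstarts, seed = seed,
                             consistency = cfac,
                             det_sequence = best$seq,
                             det_sequences = sequences))
  })
}

#' Classical mean/covariance as a robust-estimate object
#'
#' @param x numeric matrix.
#' @return A `"robust_estimate"` with `method = "classical"`.
#' @export
classical_estimate <- function(x) {
  x <- as.matrix(x)
  location <- colMeans(x)
  names(location) <- colnames(x)
  new_robust_estimate(location, ensure_pd(stats::cov(x), "classical"),
                      "classical", list())
}

#' Squared robust Mahalanobis distances
#'
#' Quadratic form `(z - mu)' Sigma^{-1} (z - mu)` per row of `x` under a
#' robust estimate; nonnegative, zero only at the location, and invariant
#' under any invertible affine map applied consistently to rows, location
#' and scatter.
#'
#' @param x numeric matrix (`n x d`), e.g. an AO matrix.
#' @param estimate a `"robust_estimate"`.
#' @return Numeric vector of length `n`.
#' @export
brmd2 <- function(x, estimate) {
  stopifnot(inherits(estimate, "robust_estimate"))
  x <- as.matrix(x)
  if (ncol(x) != length(estimate$location))
    stop("dimension mismatch between `x` and the estimate", call. = FALSE)
  R <- tryCatch(chol(estimate$scatter), error = function(e) NULL)
  if (is.null(R)) {
    sigma <- ensure_pd(estimate$scatter, "brmd2")
    R <- chol(sigma)
  }
  centred <- sweep(x, 2L, estimate$location)
  z <- backsolve(R, t(centred), transpose = TRUE)
  d2 <- colSums(z * z)
  if (!all(is.finite(d2))) stop("non-finite Mahalanobis distances", call. = FALSE)
  d2
}

#' Serialize a robust estimate to JSON
#'
#' @param estimate a `"robust_estimate"`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
robust_estimate_json <- function(estimate, path = NULL) {
  stopifnot(inherits(estimate, "robust_estimate"))
  obj <- list(location = unname(estimate$location),
              scatter = unname(estimate$scatter),
              method = estimate$method,
              meta = estimate$meta[setdiff(names(estimate$meta),
                                           c("det_sequences"))])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
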