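# Depth-weighted smoothed-bootstrap threshold and the end-to-end detector.

#' Mahalanobis depth
#'
#' Monotone transform of squared robust distances to a centrality score in
#' (0, 1]: `depth = 1 / (1 + BRMD^2)`.  Deep (central) curves get depth
#' near 1, gross outliers near 0.
#'
#' @param d2 nonnegative numeric vector of squared distances.
#' @return Depths in (0, 1].
#' @export
mahalanobis_depth <- function(d2) {
  if (any(d2 < 0)) stop("squared distances must be nonnegative", call. = FALSE)
  1 / (1 + d2)
}

#' Depth-proportional resampling probabilities
#'
#' Normalises depths to probabilities summing to 1, so the smoothed
#' bootstrap draws deep (likely clean) curves often and suspected outliers
#' rarely, keeping contamination out of the null used for the threshold.
#'
#' @param depths positive numeric vector.
#' @return Probabilities summing to 1.
#' @export
sampling_probabilities <- function(depths) {
  if (any(depths <= 0)) stop("depths must be positive", call. = FALSE)
  depths / sum(depths)
}

# Gaussian smoothing-noise sampler for one component: returns a function
# drawing an n x k noise matrix with covariance beta * cov(curves)
noise_sampler <- function(values_mat, beta) {
  sig <- stats::cov(values_mat)
  e <- eigen(beta * sig, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(sig))
  function(n) matrix(stats::rnorm(n * nrow(sig)), n) %*% t(L)
}

robust_fit <- function(ao, method, b, percents, h = NULL) {
  switch(method,
         bootstrap_mcd = bootstrap_mcd(ao, percents = percents, B = b),
         fast_mcd = fast_mcd(ao, h = h),
         stop("unknown distance method: ", method, call. = FALSE))
}

#' Smoothed-bootstrap detection threshold
#'
#' Calibrates the cut-off for squared robust Mahalanobis distances without
#' distributional assumptions.  In each of `b_outer` rounds, `n` curves
#' are resampled with replacement with depth-proportional probabilities
#' `probs`; independent Gaussian noise with covariance `beta` times the
#' empirical curve covariance (one `k x k` matrix per component) is added
#' to every resampled curve; the AO matrix, a robust estimate and the
#' squared distances of the smoothed resample are recomputed from scratch;
#' and the `quantile` of those `n` distances is taken
#' (linear-interpolation, type 7).  The threshold is the mean of the
#' `b_outer` round quantiles.
#'
#' @param x an `"fdset"` object.
#' @param probs resampling probabilities, length `n`, summing to 1.
#' @param quantile threshold quantile in (0, 1).
#' @param beta smoothing coefficient (> 0).
#' @param b_outer number of bootstrap rounds.
#' @param method `"bootstrap_mcd"` or `"fast_mcd"` for the per-round
#'   distances.
#' @param b_inner bootstrap-MCD rounds inside each outer round.
#' @param percents subsample proportions for the bootstrap-MCD.
#' @param seed optional integer seed.
#' @param max_redraw redraw cap for degenerate resamples (all curves
#'   identical).
#' @param ... further arguments passed to [ao_matrix()].
#' @return The threshold (positive scalar), with attribute
#'   `"round_quantiles"` holding the per-round quantiles.
#' @export
smoothed_bootstrap_threshold <- function(x, probs, quantile = 0.95,
                                         beta = 0.05, b_outer = 100,
                                         method = "bootstrap_mcd",
                                         b_inner = 20,
                                         percents = c(0.85, 0.90, 0.95),
                                         seed = NULL, max_redraw = 10, ...) {
  stopifnot(inherits(x, "fdset"))
  n <- dim(x$values)[1L]; p <- dim(x$values)[3L]
  if (length(probs) != n || any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("`probs` must be n nonnegative values summing to 1", call. = FALSE)
  if (quantile <= 0 || quantile >= 1) stop("`quantile` must be in (0, 1)", call. = FALSE)
  if (beta <= 0) stop("`beta` must be positive", call. = FALSE)
  if (b_outer < 1 || b_inner < 1) stop("bootstrap rounds must be >= 1", call. = FALSE)
  with_seed(seed, {
    samplers <- lapply(seq_len(p), function(j) noise_sampler(x$values[, , j], beta))
    qs <- numeric(b_outer)
    for (b in seq_len(b_outer)) {
      for (try in seq_len(max_redraw)) {
        idx <- sample.int(n, n, replace = TRUE, prob = probs)
        vals <- x$values[idx, , , drop = FALSE]
        for (j in seq_len(p)) vals[, , j] <- vals[, , j] + samplers[[j]](n)
        first <- vals[rep(1L, n), , , drop = FALSE]
        if (!isTRUE(all.equal(vals, first, tolerance = 1e-12,
                              check.attributes = FALSE))) break
        if (try == max_redraw)
          stop("degenerate resample persisted after redraws", call. = FALSE)
        warning("degenerate resample (all curves identical); redrawing", call. = FALSE)
      }
      xb <- functional_data(vals, grid = x$grid, components = x$components)
      aob <- ao_matrix(xb, ...)
      est <- robust_fit(aob, method, b_inner, percents)
      qs[b] <- stats::quantile(brmd2(aob, est), quantile, type = 7, names = FALSE)
    }
    structure(mean(qs), round_quantiles = qs)
  })
}

#' Adjusted outlyingness detection (AOD)
#'
#' Fits the full detector to a functional data set: maps each curve to its
#' AO vector ([ao_matrix()]), estimates robust location/scatter of the AO
#' cloud ([bootstrap_mcd()] or [fast_mcd()]), scores every curve by its
#' squared robust Mahalanobis distance ([brmd2()]), calibrates the
#' detection threshold by the depth-weighted smoothed bootstrap
#' ([smoothed_bootstrap_threshold()]), and flags curves whose score
#' exceeds the threshold.
#'
#' For multivariate data (`p > 1`), `mode = "joint"` runs the detector on
#' the joint `(p + 2)`-dimensional AO vector, preserving cross-component
#' dependence; `mode = "marginal"` runs the univariate detector on each
#' component (with independent sub-seeds) and flags the union, catching
#' anomalies that appear in any single dimension.
#'
#' @param x an `"fdset"` object, or a numeric matrix of univariate curves
#'   (rows) on an equidistant unit-interval grid.
#' @param quantile threshold quantile `q` in (0, 1); curves above the
#'   bootstrap `q`-quantile of squared distances are flagged.
#' @param beta smoothing coefficient of the bootstrap (default 0.05).
#' @param method `"bootstrap_mcd"` (default) or `"fast_mcd"`.
#' @param b_outer outer bootstrap rounds for the threshold.
#' @param b_inner bootstrap-MCD rounds inside each outer round.
#' @param b_score bootstrap-MCD rounds for scoring the original curves.
#' @param mode `"joint"` or `"marginal"` (only relevant for `p > 1`).
#' @param percents subsample proportions of the bootstrap-MCD.
#' @param seed optional integer; results are bit-reproducible given it.
#' @param ... passed to [ao_matrix()] (weight configuration).
#' @return An object of class `"aod"`: list with `scores` (squared robust
#'   distances of the original curves), `threshold`, logical `flags`
#'   (`flags[i]` iff `scores[i] > threshold`), `outliers` (flagged ids),
#'   `estimate`, `ao`, `config`, and for marginal mode the per-component
#'   fits in `components`.
#' @examples
#' sim <- simulate_fd(1, n = 50, contamination = 0.1, seed = 7)
#' fit <- aod(sim$data, b_outer = 20, seed = 7)
#' fit
#' table(flagged = fit$flags, truth = sim$labels)
#' @export
aod <- function(x, quantile = 0.95, beta = 0.05,
                method = c("bootstrap_mcd", "fast_mcd"),
                b_outer = 100, b_inner = 20, b_score = 100,
                mode = c("joint", "marginal"),
                percents = c(0.85, 0.90, 0.95), seed = NULL, ...) {
  if (is.matrix(x)) x <- functional_data(x)
  stopifnot(inherits(x, "fdset"))
  method <- match.arg(method)
  mode <- match.arg(mode)
  p <- dim(x$values)[3L]
  config <- list(quantile = quantile, beta = beta, method = method,
                 b_outer = b_outer, b_inner = b_inner, b_score = b_score,
                 mode = mode, percents = percents, seed = seed)
  if (p > 1L && mode == "marginal") {
    subseeds <- if (is.null(seed)) vector("list", p) else
      with_seed(seed, as.list(split_seeds(p)))
    comps <- lapply(seq_len(p), function(j)
      aod(fd_component(x, j), quantile = quantile, beta = beta,
          method = method, b_outer = b_outer, b_inner = b_inner,
          b_score = b_score, percents = percents, seed = subseeds[[j]], ...))
    flags <- Reduce(`|`, lapply(comps, `[[`, "flags"))
    # per-curve score on a common scale: max over components of the
    # score/threshold ratio, so flags <=> scores > threshold still holds
    ratio <- do.call(pmax, lapply(comps, function(f) f$scores / f$threshold))
    out <- list(scores = ratio, threshold = 1, flags = flags,
                outliers = x$ids[flags], estimate = NULL, ao = NULL,
                components = comps, config = config, ids = x$ids, data = x)
    return(structure(out, class = "aod"))
  }
  fit_one <- function() {
    ao <- ao_matrix(x, ...)
    est <- robust_fit(ao, method, b_score, percents)
    scores <- brmd2(ao, est)
    probs <- sampling_probabilities(mahalanobis_depth(scores))
    threshold <- smoothed_bootstrap_threshold(
      x, probs, quantile = quantile, beta = beta, b_outer = b_outer,
      method = method, b_inner = b_inner, percents = percents, ...)
    flags <- scores > threshold
    list(scores = scores, threshold = as.numeric(threshold), flags = flags,
         round_quantiles = attr(threshold, "round_quantiles"),
         outliers = x$ids[flags], estimate = est, ao = ao,
         components = NULL, config = config, ids = x$ids, data = x)
  }
  structure(with_seed(seed, fit_one()), class = "aod")
}

#' @export
print.aod <- function(x, ...) {
  n <- length(x$scores)
  cat(sprintf("Adjusted outlyingness detection (%s, %s mode)\n",
              x$config$method, x$config$mode))
  cat(sprintf("  %d curves, threshold %.4g (q = %.3g): %d flagged\n",
              n, x$threshold, x$config$quantile, sum(x$flags)))
  if (any(x$flags))
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.aod <- function(object, ...) {
  df <- data.frame(curve_id = object$ids,
                   score = object$scores,
                   flagged = object$flags, row.names = NULL)
  df <- df[order(-df$score), ]
  structure(list(table = df, threshold = object$threshold,
                 config = object$config), class = "summary.aod")
}

#' @export
print.summary.aod <- function(x, ...) {
  cat(sprintf("AOD summary: threshold %.4g, %d of %d curves flagged\n",
              x$threshold, sum(x$table$flagged), nrow(x$table)))
  print(utils::head(x$table, 10), row.names = FALSE)
  if (nrow(x$table) > 10) cat("  ...\n")
  invisible(x)
}

#' Plot a fitted AOD detector
#'
#' Draws the curves with flagged outliers highlighted and, alongside, the
#' per-curve squared robust distances against the bootstrap threshold.
#'
#' @param x an `"aod"` object fitted on data retained in the fit.
#' @param component which component of multivariate data to draw.
#' @param ... further graphical parameters passed to [plot.fdset()].
#' @return `x`, invisibly.
#' @export
plot.aod <- function(x, component = 1L, ...) {
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  cols <- ifelse(x$flags, "red", "grey60")
  plot(x$data, col = cols, component = component,
       main = "curves (outliers in red)", ...)
  plot(x$scores, col = cols, pch = 19, xlab = "curve", ylab = "score",
       main = sprintf("scores vs threshold (q = %.2f)", x$config$quantile))
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' @export
as.data.frame.aod <- function(x, ...) {
  data.frame(curve_id = x$ids, score = x$scores, flagged = x$flags,
             row.names = NULL)
}
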