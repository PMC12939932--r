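#' Directional outlyingness curves
#'
#' Pointwise robust standardised deviation of each curve times the spatial
#' sign of its deviation from the cross-sectional median.  Componentwise,
#' `o_j(t) = (X_j(t) - median_j(t)) / scale_j(t)`; the directional
#' outlyingness is `O(t) = ||o(t)|| * v(t)` with spatial sign
#' `v(t) = (X(t) - median(t)) / ||X(t) - median(t)||` (and `O(t) = 0` where
#' the curve sits exactly at the median).  For `p = 1` this reduces to the
#' signed scalar `(X(t) - median(t)) / scale(t)`.
#'
#' Scale is the pointwise unscaled MAD by default.  A zero scale at
#' isolated grid points would leave the outlyingness undefined there; such
#' points are floored to the smallest positive scale observed on that
#' component (with a warning), which keeps the curves finite without
#' discarding the point.
#'
#' @param x an `"fdset"` object.
#' @param summary optional `"fd_summary"` of kind `"median_mad"` computed
#'   on `x`; computed internally when missing.
#' @param mad_constant passed to [fd_summary()] when `summary` is missing.
#' @return Class `"dirout"`: list with `values` (`n x k x p` array of
#'   `O`), `grid` and `components`.
#' @export
directional_outlyingness <- function(x, summary = NULL, mad_constant = 1) {
  stopifnot(inherits(x, "fdset"))
  if (is.null(summary)) summary <- fd_summary(x, "median_mad", mad_constant)
  if (!inherits(summary, "fd_summary") || summary$kind != "median_mad")
    stop("`summary` must be an fd_summary of kind \"median_mad\"", call. = FALSE)
  if (length(summary$grid) != length(x$grid) ||
      any(summary$grid != x$grid) || nrow(summary$location) != length(x$grid))
    stop("summary grid does not match the data grid", call. = FALSE)
  n <- dim(x$values)[1L]; k <- dim(x$values)[2L]; p <- dim(x$values)[3L]
  sca <- summary$scale
  if (any(sca <= 0)) {
    for (j in seq_len(p)) {
      z <- sca[, j] <= 0
      if (any(z)) {
        pos <- sca[!z, j]
        if (!length(pos))
          stop(sprintf("degenerate data: component %s has zero scale at every grid point",
                       x$components[j]), call. = FALSE)
        sca[z, j] <- min(pos)
      }
    }
    warning("zero pointwise scale at some grid points; floored to the smallest positive scale on the component",
            call. = FALSE)
  }
  dev <- x$values - rep(summary$location, each = n)  # X - median, n x k x p
  o <- dev / rep(sca, each = n)                      # componentwise scaled
  if (p == 1L) {
    O <- o
  } else {
    onorm2 <- devnorm2 <- matrix(0, n, k)
    for (j in seq_len(p)) {
      onorm2 <- onorm2 + o[, , j]^2
      devnorm2 <- devnorm2 + dev[, , j]^2
    }
    fac <- sqrt(onorm2) / sqrt(devnorm2)  # ||o|| / ||X - median||
    fac[devnorm2 == 0] <- 0               # curve at the median: O = 0
    O <- dev * as.vector(fac)
  }
  structure(list(values = O, grid = x$grid, components = x$components),
            class = "dirout")
}

as_dirout <- function(O, grid) {
  if (inherits(O, "dirout")) return(O)
  if (is.matrix(O)) O <- array(O, c(nrow(O), ncol(O), 1L))
  structure(list(values = O, grid = grid,
                 components = paste0("X", seq_len(dim(O)[3L]))),
            class = "dirout")
}

check_weight <- function(w, O) {
  if (!inherits(w, "fd_weight")) stop("`w` must be an fd_weight", call. = FALSE)
  if (nrow(w$values) != dim(O$values)[2L] || ncol(w$values) != dim(O$values)[3L])
    stop("weight dimensions do not match the outlyingness array", call. = FALSE)
}

#' Adjusted mean of directional outlyingness (AMO)
#'
#' Componentwise weighted integral of the directional outlyingness curve,
#' `AMO_j = int O_j(t) w_j(t) dt`.  With the uniform weight this is the
#' unweighted mean directional outlyingness (MO); with the data-driven
#' weights, symmetric deviations no longer cancel, so partial anomalies in
#' high-variability regions leave a visible signature.
#'
#' @param O a `"dirout"` object (or `n x k` matrix with `grid` attribute
#'   taken from `w`).
#' @param w an `"fd_weight"`.
#' @return `n x p` matrix of weighted means, with attribute
#'   `"weight_source"` recording which weight produced it.
#' @export
amo <- function(O, w) {
  O <- as_dirout(O, w$grid)
  check_weight(w, O)
  p <- dim(O$values)[3L]
  tw <- trapz_weights(O$grid)
  out <- matrix(0, dim(O$values)[1L], p)
  for (j in seq_len(p)) out[, j] <- O$values[, , j] %*% (w$values[, j] * tw)
  colnames(out) <- O$components
  attr(out, "weight_source") <- w$source
  out
}

#' Adjusted variance of directional outlyingness (AVO)
#'
#' Weighted dispersion of the outlyingness curve about its own weighted
#' mean, summed over components:
#' `AVO = sum_j int (O_j(t) - AMO_j)^2 w_j(t) dt`.  Always nonnegative.
#' The reference mean must have been computed with the *same* weight as
#' `w` (the weighted mean/variance pairs are defined jointly).
#'
#' @param O a `"dirout"` object.
#' @param w an `"fd_weight"`.
#' @param amo_ref `n x p` matrix from [amo()] computed with weight `w`;
#'   recomputed internally when missing.
#' @return Numeric vector of length `n`, nonnegative.
#' @export
avo <- function(O, w, amo_ref = NULL) {
  O <- as_dirout(O, w$grid)
  check_weight(w, O)
  if (is.null(amo_ref)) amo_ref <- amo(O, w)
  src <- attr(amo_ref, "weight_source")
  if (is.null(src) || !identical(src, w$source))
    stop("`amo_ref` was not computed with the same weight as `w`", call. = FALSE)
  n <- dim(O$values)[1L]; p <- dim(O$values)[3L]
  tw <- trapz_weights(O$grid)
  out <- numeric(n)
  for (j in seq_len(p))
    out <- out + (O$values[, , j] - amo_ref[, j])^2 %*% (w$values[, j] * tw)
  drop(out)
}

#' Skewness of directional outlyingness (SO)
#'
#' Third-order functional of the outlyingness curve,
#' `SO = (1/lambda) sum_j int ((O_j(t) - MO_j) / VO_j^(1/2))^3 dt`, where
#' `MO` and `VO` are the mean and variation of directional outlyingness
#' under the uniform weight, and `lambda` is the domain length.  It captures the
#' magnitude *and* sign of the asymmetry of a curve's outlyingness, which
#' lower-order moments miss; mirroring a curve about the pointwise median
#' flips the sign of its SO.
#'
#' The default normalisation `"sd"` divides the centred outlyingness by
#' `VO^(1/2)` inside the cube (the conventional standardized skewness, so
#' nominal curves keep light-tailed SO values); `normalization =
#' "variance"` instead divides by the variation `VO` itself.  A component with
#' `VO_j = 0` (constant outlyingness curve) contributes 0, the limit
#' convention for a degenerate direction.
#'
#' @param O a `"dirout"` object.
#' @param weight weight used inside `MO`/`VO`; the uniform weight by
#'   default.
#' @param normalization `"sd"` (default) or `"variance"`.
#' @return Numeric vector of length `n`.
#' @export
so <- function(O, weight = NULL,
               normalization = c("sd", "variance")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(O, "dirout"))
  n <- dim(O$values)[1L]; p <- dim(O$values)[3L]
  g <- O$grid
  lambda <- diff(range(g))
  if (is.null(weight)) {
    wv <- matrix(1 / lambda, length(g), p)
    weight <- structure(list(values = wv, source = "uniform", grid = g),
                        class = "fd_weight")
  }
  check_weight(weight, O)
  mo <- amo(O, weight)
  vo <- matrix(0, n, p)
  tw <- trapz_weights(g)
  for (j in seq_len(p))
    vo[, j] <- (O$values[, , j] - mo[, j])^2 %*% (weight$values[, j] * tw)
  out <- numeric(n)
  for (j in seq_len(p)) {
    denom <- if (normalization == "variance") vo[, j] else sqrt(vo[, j])
    centred <- matrix(O$values[, , j], n) - mo[, j]
    ratio <- centred / denom
    ratio[denom == 0, ] <- 0
    out <- out + (ratio^3 %*% tw) / lambda
  }
  drop(out)
}

#' Adjusted outlyingness matrix
#'
#' Maps every curve to its adjusted outlyingness (AO) vector
#' `(AMO_1, ..., AMO_p, AVO, SO)`: the w1-weighted mean outlyingness per
#' component, the w2-weighted (derivative-informed) variance, and the
#' skewness functional.  This reduces functional outlier detection to a
#' multivariate problem in `p + 2` dimensions while retaining position,
#' shape and asymmetry information.
#'
#' @param x an `"fdset"` object.
#' @param amo_weight weight for the mean component (default `"w1"`).
#' @param avo_weight weight for the variance component (default `"w2"`).
#' @param so_weight weight used inside the skewness functional's `MO`/`VO`
#'   (default `"uniform"`).
#' @param so_normalization passed to [so()].
#' @param mad_constant MAD scaling for the underlying directional
#'   outlyingness.
#' @return `n x (p + 2)` matrix with columns `AMO_1..AMO_p, AVO, SO` and
#'   rownames the curve ids; attribute `"weights"` records the
#'   configuration.
#' @examples
#' sim <- simulate_fd(0, n = 60, contamination = 0.1, seed = 1)
#' head(ao_matrix(sim$data))
#' @export
ao_matrix <- function(x, amo_weight = "w1", avo_weight = "w2",
                      so_weight = "uniform",
                      so_normalization = c("sd", "variance"),
                      mad_constant = 1) {
  stopifnot(inherits(x, "fdset"))
  so_normalization <- match.arg(so_normalization)
  w_amo <- fd_weight(x, amo_weight)
  w_avo <- fd_weight(x, avo_weight)
  w_so <- fd_weight(x, so_weight)
  O <- directional_outlyingness(x, mad_constant = mad_constant)
  a1 <- amo(O, w_amo)
  a2 <- if (identical(avo_weight, amo_weight)) a1 else amo(O, w_avo)
  v <- avo(O, w_avo, a2)
  s <- so(O, w_so, so_normalization)
  out <- cbind(a1, AVO = v, SO = s)
  colnames(out) <- c(paste0("AMO_", seq_len(ncol(a1))), "AVO", "SO")
  rownames(out) <- x$ids
  attr(out, "weights") <- list(amo = amo_weight, avo = avo_weight,
                               so = so_weight)
  out
}

#' Write an AO matrix to CSV
#'
#' @param ao matrix from [ao_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ao_csv <- function(ao, path) {
  df <- data.frame(ao, check.names = FALSE)
  df$curve_id <- rownames(ao)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
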