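#' Functional data on a common grid
#'
#' Container for `n` curves observed at `k` shared grid points with `p`
#' components per curve.  All statistics in the package consume this
#' object.  Curves must share one strictly increasing grid (a regular
#' design); irregular designs are rejected, as the method requires curves
#' aligned onto a common grid.
#'
#' @param values numeric matrix (`n x k`, univariate) or 3-d array
#'   (`n x k x p`) of curve values; all entries must be finite.
#' @param grid numeric vector of `k` strictly increasing time points.
#'   Defaults to `k` equidistant points on `[0, 1]`.
#' @param ids optional curve identifiers (length `n`).
#' @param components optional component names (length `p`).
#'
#' @return An object of class `"fdset"`: a list with elements `values`
#'   (`n x k x p` array), `grid`, `ids` and `components`.
#' @examples
#' x <- functional_data(matrix(rnorm(50 * 20), 50, 20))
#' x
#' @export
functional_data <- function(values, grid = NULL, ids = NULL, components = NULL) {
  if (is.matrix(values)) values <- array(values, c(nrow(values), ncol(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be an n x k matrix or an n x k x p array", call. = FALSE)
  storage.mode(values) <- "double"
  n <- dim(values)[1L]; k <- dim(values)[2L]; p <- dim(values)[3L]
  if (n < 2L) stop("need at least 2 curves", call. = FALSE)
  if (k < 3L) stop("need at least 3 grid points", call. = FALSE)
  if (!all(is.finite(values))) stop("all curve values must be finite", call. = FALSE)
  if (is.null(grid)) grid <- seq(0, 1, length.out = k)
  grid <- as.double(grid)
  if (length(grid) != k) stop("grid length must match the number of columns of `values`", call. = FALSE)
  if (any(diff(grid) <= 0)) stop("grid points must be strictly increasing", call. = FALSE)
  if (is.null(ids)) ids <- paste0("curve_", seq_len(n))
  if (length(ids) != n) stop("`ids` must have one entry per curve", call. = FALSE)
  if (is.null(components)) components <- paste0("X", seq_len(p))
  if (length(components) != p) stop("`components` must have one entry per component", call. = FALSE)
  dimnames(values) <- list(as.character(ids), NULL, components)
  structure(list(values = values, grid = grid, ids = as.character(ids),
                 components = components),
            class = "fdset")
}

#' @export
print.fdset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Functional data set: %d curves, %d grid points, %d component%s\n",
              d[1L], d[2L], d[3L], if (d[3L] > 1L) "s" else ""))
  cat(sprintf("  domain: [%g, %g]\n", x$grid[1L], x$grid[length(x$grid)]))
  invisible(x)
}

#' @export
dim.fdset <- function(x) dim(x$values)

#' Subset curves of a functional data set
#'
#' @param x an `"fdset"` object.
#' @param i curve index (logical, integer or character).
#' @param ... ignored.
#' @return An `"fdset"` with the selected curves.
#' @export
`[.fdset` <- function(x, i, ...) {
  functional_data(x$values[i, , , drop = FALSE], grid = x$grid,
                  ids = x$ids[i], components = x$components)
}

#' Extract one component of a multivariate functional data set
#'
#' @param x an `"fdset"` object.
#' @param j component index or name.
#' @return A univariate `"fdset"`.
#' @export
fd_component <- function(x, j) {
  stopifnot(inherits(x, "fdset"))
  functional_data(x$values[, , j, drop = FALSE], grid = x$grid, ids = x$ids,
                  components = x$components[j])
}

#' Plot functional data
#'
#' @param x an `"fdset"` object.
#' @param col vector of line colours, recycled over curves.
#' @param component which component to draw.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.fdset <- function(x, col = "grey40", component = 1L, ...) {
  graphics::matplot(x$grid, t(x$values[, , component]), type = "l", lty = 1,
                    col = col, xlab = "t", ylab = x$components[component], ...)
  invisible(x)
}

# composite trapezoid quadrature weights for a strictly increasing grid
trapz_weights <- function(grid) {
  d <- diff(grid)
  c(d, 0) / 2 + c(0, d) / 2
}

#' Trapezoidal integration on a grid
#'
#' Integrates discretely observed curves over their domain with the
#' composite trapezoidal rule (exact for the piecewise-linear
#' interpolant).  Every integral in the outlyingness functionals uses
#' this rule.
#'
#' @param y numeric vector of length `k`, or a matrix whose *rows* are
#'   curves sampled on `grid`.
#' @param grid strictly increasing numeric vector of length `k` (k >= 2).
#' @return A single number, or one integral per row of `y`.
#' @examples
#' grid_integrate(c(1, 2, 1), c(0, 0.5, 1))  # 1.5
#' @export
grid_integrate <- function(y, grid) {
  grid <- as.double(grid)
  if (length(grid) < 2L || any(diff(grid) <= 0))
    stop("grid must be strictly increasing with at least 2 points", call. = FALSE)
  w <- trapz_weights(grid)
  if (is.matrix(y)) {
    if (ncol(y) != length(grid)) stop("curve length does not match the grid", call. = FALSE)
    return(drop(y %*% w))
  }
  if (length(y) != length(grid)) stop("curve length does not match the grid", call. = FALSE)
  sum(y * w)
}

#' Differentiate functional data
#'
#' Per-curve numerical derivative on the same grid: central differences at
#' interior points, one-sided differences at the endpoints.  Exact for
#' linear curves.  No pre-smoothing is applied.
#'
#' @param x an `"fdset"` object with at least 3 grid points.
#' @return An `"fdset"` holding the derivative curves.
#' @export
fd_derivative <- function(x) {
  stopifnot(inherits(x, "fdset"))
  g <- x$grid; k <- length(g)
  if (k < 3L) stop("need at least 3 grid points to differentiate", call. = FALSE)
  v <- x$values
  dv <- v
  for (j in seq_len(dim(v)[3L])) {
    m <- v[, , j]
    d <- m
    d[, 1L] <- (m[, 2L] - m[, 1L]) / (g[2L] - g[1L])
    d[, k] <- (m[, k] - m[, k - 1L]) / (g[k] - g[k - 1L])
    int <- 2:(k - 1L)
    d[, int] <- (m[, int + 1L] - m[, int - 1L]) /
      rep(g[int + 1L] - g[int - 1L], each = nrow(m))
    dv[, , j] <- d
  }
  functional_data(dv, grid = g, ids = x$ids, components = x$components)
}

# fast column sds of a matrix (n-1 denominator); centred for stability so
# exactly identical columns give an exact zero
col_sds <- function(m) {
  xc <- m - rep(colMeans(m), each = nrow(m))
  sqrt(colSums(xc * xc) / (nrow(m) - 1))
}

col_medians <- function(m) apply(m, 2L, stats::median)

#' Pointwise cross-curve location and scale
#'
#' Per grid point and component, the location and scale of the values
#' across curves: median and median absolute deviation for
#' `kind = "median_mad"` (the robust pair used inside directional
#' outlyingness) or mean and standard deviation for `kind = "mean_sd"`
#' (used by the data-driven weights).  The MAD is *unscaled* by default
#' (no 1.4826 consistency factor); set `mad_constant = 1.4826` for the
#' Gaussian-consistent version.
#'
#' @param x an `"fdset"` object.
#' @param kind `"median_mad"` or `"mean_sd"`.
#' @param mad_constant multiplier applied to the raw MAD.
#' @return An object of class `"fd_summary"`: list with `location` and
#'   `scale` (`k x p` matrices) and `kind`.  Zero scales are legal here and
#'   handled downstream.
#' @export
fd_summary <- function(x, kind = c("median_mad", "mean_sd"), mad_constant = 1) {
  stopifnot(inherits(x, "fdset"))
  kind <- match.arg(kind)
  p <- dim(x$values)[3L]; k <- length(x$grid)
  loc <- sca <- matrix(0, k, p)
  for (j in seq_len(p)) {
    m <- x$values[, , j]
    if (kind == "median_mad") {
      loc[, j] <- col_medians(m)
      sca[, j] <- mad_constant *
        col_medians(abs(m - rep(loc[, j], each = nrow(m))))
    } else {
      loc[, j] <- colMeans(m)
      sca[, j] <- col_sds(m)
    }
  }
  structure(list(location = loc, scale = sca, kind = kind, grid = x$grid),
            class = "fd_summary")
}

#' Data-driven weight functions
#'
#' Nonnegative per-component weight curves integrating to 1 over the
#' domain.  `"w1"` is the pointwise standard deviation of the curves,
#' normalised by its integral: it up-weights regions where the sample
#' disperses, where outlyingness is most informative.  `"w2"` applies the
#' same construction to the derivative curves, concentrating mass where
#' the *shape* (rate of change) varies across curves.  `"uniform"` is the
#' constant weight 1/lambda(I), under which the weighted moments reduce to
#' the unweighted mean and variation of directional outlyingness.
#'
#' @param x an `"fdset"` object.
#' @param type `"w1"`, `"w2"` or `"uniform"`.
#' @return Class `"fd_weight"`: list with `values` (`k x p` matrix),
#'   `source` and `grid`.  Each column integrates to 1 (trapezoid rule).
#' @examples
#' x <- functional_data(matrix(rnorm(40 * 15), 40, 15))
#' w <- fd_weight(x, "w1")
#' grid_integrate(w$values[, 1], w$grid)  # 1
#' @export
fd_weight <- function(x, type = c("w1", "w2", "uniform")) {
  stopifnot(inherits(x, "fdset"))
  type <- match.arg(type)
  k <- length(x$grid); p <- dim(x$values)[3L]
  if (type == "uniform") {
    lambda <- diff(range(x$grid))
    vals <- matrix(1 / lambda, k, p)
  } else {
    basis <- if (type == "w1") x else fd_derivative(x)
    s <- fd_summary(basis, "mean_sd")$scale
    vals <- matrix(0, k, p)
    scale_ref <- max(abs(basis$values), 1e-8)
    for (j in seq_len(p)) {
      tot <- grid_integrate(s[, j], x$grid)
      if (tot <= 1e-12 * scale_ref)
        stop(sprintf(
          "degenerate data: component %s has zero %s everywhere, weight %s is undefined",
          x$components[j],
          if (type == "w1") "pointwise sd" else "derivative sd", type),
          call. = FALSE)
      vals[, j] <- s[, j] / tot
    }
  }
  structure(list(values = vals, source = type, grid = x$grid),
            class = "fd_weight")
}
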