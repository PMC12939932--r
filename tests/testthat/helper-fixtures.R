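# Shared fixtures and independent oracle helpers, built in code.

# independent trapezoid oracle (loop form, no shared code path)
trapz_oracle <- function(y, grid) {
  s <- 0
  for (i in seq_len(length(grid) - 1))
    s <- s + (grid[i + 1] - grid[i]) * (y[i] + y[i + 1]) / 2
  s
}

# small deterministic functional data set: smooth curves + noise
toy_fd <- function(n = 20, k = 15, p = 1, seed = 1) {
  set.seed(seed)
  grid <- seq(0, 1, length.out = k)
  vals <- array(0, c(n, k, p))
  for (j in seq_len(p))
    vals[, , j] <- outer(rnorm(n, 0, 0.5), rep(1, k)) +
      matrix(rep(j * grid, each = n), n, k) + matrix(rnorm(n * k, 0, 0.2), n, k)
  functional_data(vals, grid = grid)
}

# wrap a plain matrix of outlyingness curves as a dirout object
as_dirout_fixture <- function(m, grid, p = 1) {
  structure(list(values = array(m, c(nrow(m), ncol(m), p)), grid = grid,
                 components = paste0("X", seq_len(p))),
            class = "dirout")
}

expect_all_equal <- function(x, y, tol = 1e-12) {
  expect_true(max(abs(x - y)) < tol)
}
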