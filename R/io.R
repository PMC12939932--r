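# CSV readers/writers for functional data on a common grid.

fmt17 <- function(x) sprintf("%.17g", x)

#' Read functional data from CSV
#'
#' Two layouts are supported.  *Wide*: columns `curve_id`, `component`
#' (optional for univariate data) and one column per grid point, named by
#' its numeric `t` value; one row per curve per component.  *Long*:
#' columns `curve_id`, `component`, `t`, `value`.  Both readers validate
#' the common-grid requirement: every curve and component must be
#' observed at exactly the same grid points (the detector operates on a
#' regular, shared design; align irregular data onto a common grid before
#' reading).  Unsorted grid columns are sorted with a warning.
#'
#' @param path CSV file.
#' @param format `"wide"` or `"long"`.
#' @return An `"fdset"` object.
#' @export
read_fd_csv <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "wide") {
    if (!"curve_id" %in% names(df))
      stop("wide format needs a `curve_id` column", call. = FALSE)
    if (!"component" %in% names(df)) df$component <- "X1"
    tcols <- setdiff(names(df), c("curve_id", "component"))
    grid <- suppressWarnings(as.numeric(tcols))
    if (anyNA(grid))
      stop("wide-format grid columns must have numeric names", call. = FALSE)
    if (any(diff(grid) <= 0)) {
      if (anyDuplicated(grid)) stop("duplicated grid columns", call. = FALSE)
      warning("grid columns were not sorted; sorting by t", call. = FALSE)
      ord <- order(grid)
      grid <- grid[ord]; tcols <- tcols[ord]
    }
    ids <- unique(df$curve_id)
    comps <- unique(df$component)
    vals <- array(NA_real_, c(length(ids), length(grid), length(comps)))
    for (r in seq_len(nrow(df))) {
      i <- match(df$curve_id[r], ids); j <- match(df$component[r], comps)
      if (!all(is.na(vals[i, , j])))
        stop("duplicated (curve, component) row in wide file", call. = FALSE)
      vals[i, , j] <- as.numeric(df[r, tcols])
    }
    if (anyNA(vals))
      stop("incomplete wide file: every curve needs every component on the shared grid",
           call. = FALSE)
    return(functional_data(vals, grid = grid, ids = ids, components = comps))
  }
  need <- c("curve_id", "t", "value")
  if (!all(need %in% names(df)))
    stop("long format needs columns curve_id, t, value", call. = FALSE)
  if (!"component" %in% names(df)) df$component <- "X1"
  ids <- unique(df$curve_id)
  comps <- unique(df$component)
  grid <- sort(unique(as.numeric(df$t)))
  vals <- array(NA_real_, c(length(ids), length(grid), length(comps)))
  i <- match(df$curve_id, ids); j <- match(df$component, comps)
  tt <- match(as.numeric(df$t), grid)
  vals[cbind(i, tt, j)] <- as.numeric(df$value)
  if (anyNA(vals))
    stop(paste("curves are not aligned on a common grid: every (curve, component)",
               "must be observed at every t; align or interpolate first"),
         call. = FALSE)
  functional_data(vals, grid = grid, ids = ids, components = comps)
}

#' Write functional data to CSV
#'
#' Inverse of [read_fd_csv()].  Values are serialised with 17 significant
#' digits, so a write/read roundtrip is lossless at double precision.
#'
#' @param x an `"fdset"` object.
#' @param path output file.
#' @param format `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_fd_csv <- function(x, path, format = c("wide", "long")) {
  stopifnot(inherits(x, "fdset"))
  format <- match.arg(format)
  n <- dim(x$values)[1L]; k <- dim(x$values)[2L]; p <- dim(x$values)[3L]
  con <- file(path, "w"); on.exit(close(con))
  if (format == "wide") {
    writeLines(paste(c("curve_id", "component", fmt17(x$grid)),
                     collapse = ","), con)
    for (j in seq_len(p)) for (i in seq_len(n))
      writeLines(paste(c(x$ids[i], x$components[j], fmt17(x$values[i, , j])),
                       collapse = ","), con)
  } else {
    writeLines("curve_id,component,t,value", con)
    for (j in seq_len(p)) for (i in seq_len(n))
      writeLines(paste(x$ids[i], x$components[j], fmt17(x$grid),
                       fmt17(x$values[i, , j]), sep = ","), con)
  }
  invisible(path)
}
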