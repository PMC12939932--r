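# Confusion metrics, ROC/AUC and the replication harness.

#' Confusion metrics for a detection run
#'
#' Given flagged curves and ground-truth labels: true positive rate
#' `pc = TP / P` (proportion of true outliers detected), false positive
#' rate `pf = FP / N` (proportion of nominal curves flagged), `precision
#' = TP / (TP + FP)` (defined as 0 when nothing is flagged, so F1 stays
#' defined) and the F1 score (harmonic mean of precision and pc; 0 when
#' both are 0).
#'
#' @param flags logical vector of detector decisions.
#' @param labels logical vector of true outlier indicators.
#' @return A list of class `"aod_metrics"`: `pc`, `pf`, `precision`, `f1`
#'   and the raw counts `tp`, `fp`, `fn`, `tn`.
#' @examples
#' # 12 true outliers, 10 detected, no false flags
#' confusion_rates(c(rep(TRUE, 10), rep(FALSE, 30)),
#'                 c(rep(TRUE, 12), rep(FALSE, 28)))
#' @export
confusion_rates <- function(flags, labels) {
  flags <- as.logical(flags); labels <- as.logical(labels)
  if (length(flags) != length(labels))
    stop("`flags` and `labels` must have equal length", call. = FALSE)
  if (anyNA(flags) || anyNA(labels)) stop("missing values not allowed", call. = FALSE)
  P <- sum(labels); N <- sum(!labels)
  if (P == 0) stop("no true outliers: the true positive rate is undefined", call. = FALSE)
  if (N == 0) stop("no nominal curves: the false positive rate is undefined", call. = FALSE)
  tp <- sum(flags & labels); fp <- sum(flags & !labels)
  pc <- tp / P
  pf <- fp / N
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (precision + pc == 0) 0 else 2 * precision * pc / (precision + pc)
  structure(list(pc = pc, pf = pf, precision = precision, f1 = f1,
                 tp = tp, fp = fp, fn = P - tp, tn = N - fp),
            class = "aod_metrics")
}

#' @export
print.aod_metrics <- function(x, ...) {
  cat(sprintf("pc = %.4f  pf = %.4f  precision = %.4f  F1 = %.4f\n",
              x$pc, x$pf, x$precision, x$f1))
  invisible(x)
}

#' Area under the ROC curve of a score
#'
#' Treats the per-curve scores (e.g. squared robust distances) as a
#' ranking of outlyingness and computes the area under the ROC curve via
#' the Mann-Whitney statistic, with tied scores handled by average ranks.
#'
#' @param scores numeric outlyingness scores (higher = more outlying).
#' @param labels logical true-outlier indicators; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - P * (P + 1) / 2) / (P * N)
}

#' Replicate a simulation-detection experiment
#'
#' Runs `simulate -> detect -> score` for `reps` independent replicates on
#' split seeds and averages the metrics, mirroring the benchmark protocol
#' of repeated simulation with averaged true/false positive rates.
#'
#' @param model benchmark model id (`0:15`), passed to [simulate_fd()].
#' @param contamination outlier proportion.
#' @param n,k simulation size (see [simulate_fd()] for defaults).
#' @param reps number of replicates.
#' @param seed optional integer master seed; replicate seeds are split
#'   from it, so the whole experiment is reproducible.
#' @param auc also compute the AUC of the scores per replicate.
#' @param mode detection mode for multivariate data, passed to [aod()].
#' @param ... further detector settings passed to [aod()] (e.g.
#'   `quantile`, `beta`, `method`, `b_outer`, `b_inner`).
#' @return Class `"aod_eval"`: list with `mean` and `sd` (named vectors
#'   over pc, pf, precision, f1 and optionally auc), `reps`, `per_rep`
#'   (replicate-by-metric matrix) and the experiment settings.
#' @examples
#' \donttest{
#' ev <- replicate_experiment(1, contamination = 0.1, reps = 5, seed = 1,
#'                            b_outer = 20)
#' ev
#' }
#' @export
replicate_experiment <- function(model, contamination, n = 100, k = NULL,
                                 reps = 50, seed = NULL, auc = FALSE,
                                 mode = "joint", ...) {
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  seeds <- if (is.null(seed)) replicate(reps, NULL, simplify = FALSE) else
    with_seed(seed, as.list(matrix(split_seeds(2 * reps), 2)))
  metrics <- c("pc", "pf", "precision", "f1", if (auc) "auc")
  per_rep <- matrix(NA_real_, reps, length(metrics),
                    dimnames = list(NULL, metrics))
  for (r in seq_len(reps)) {
    sim_seed <- if (is.null(seed)) NULL else seeds[[2 * r - 1]]
    fit_seed <- if (is.null(seed)) NULL else seeds[[2 * r]]
    sim <- simulate_fd(model, n = n, k = k, contamination = contamination,
                       seed = sim_seed)
    fit <- aod(sim$data, seed = fit_seed, mode = mode, ...)
    m <- confusion_rates(fit$flags, sim$labels)
    per_rep[r, c("pc", "pf", "precision", "f1")] <-
      c(m$pc, m$pf, m$precision, m$f1)
    if (auc) per_rep[r, "auc"] <- roc_auc(fit$scores, sim$labels)
  }
  structure(list(mean = colMeans(per_rep), sd = apply(per_rep, 2, stats::sd),
                 reps = reps, per_rep = per_rep, model = model,
                 contamination = contamination, n = n, k = k, seed = seed,
                 detector = list(...)),
            class = "aod_eval")
}

#' @export
print.aod_eval <- function(x, ...) {
  cat(sprintf("Model %s, c = %g, n = %d, %d replicates\n",
              x$model, x$contamination, x$n, x$reps))
  tab <- rbind(mean = x$mean, sd = x$sd)
  print(round(tab, 4))
  invisible(x)
}
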