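# Method-comparison statistics: Pearson correlation with Fisher-z CI,
# percent bias with bootstrap CI, mean (absolute) difference, event-level
# F-measure, 3-SD outlier sensitivity and the strict r > 0.75 optimization
# gate. `pairs` throughout is a data.frame with columns `hybrid` and
# `manual` holding the two methods' per-sample values for one population
# (absolute counts in 10^9 cells/L, or percent of parent).

checkPairs <- function(pairs) {
  if (!all(c("hybrid", "manual") %in% names(pairs)))
    preconditionError("pairs must have columns 'hybrid' and 'manual'")
  pairs
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param pairs data.frame with columns `hybrid`, `manual` (n >= 4 paired
#'   samples).
#' @param level confidence level.
#' @return Named numeric `c(r, lo, hi)`; the CI uses
#'   `atanh(r) +/- z / sqrt(n - 3)`.
#' @export
pearsonCI <- function(pairs, level = 0.95) {
  pairs <- checkPairs(pairs)
  n <- nrow(pairs)
  if (n < 4) preconditionError("correlation needs at least 4 paired samples")
  if (stats::sd(pairs$hybrid) == 0 || stats::sd(pairs$manual) == 0)
    preconditionError("correlation undefined: one method's values are constant")
  r <- stats::cor(pairs$hybrid, pairs$manual)
  if (abs(r) >= 1) return(c(r = r, lo = r, hi = r))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  c(r = r, lo = tanh(z - q * se), hi = tanh(z + q * se))
}

#' Percent bias of the hybrid method against the manual gold standard
#'
#' Defined as the relative difference of method means,
#' `100 * (mean(hybrid) - mean(manual)) / mean(manual)`; a positive value
#' indicates positive bias in the automated analysis. The alternative
#' mean-of-per-sample-ratios definition is available via `method`. The CI
#' is a nonparametric bootstrap over paired rows (percentile, fixed seed).
#'
#' @param pairs data.frame with columns `hybrid`, `manual`.
#' @param method `"ratio_of_means"` (default, robust to near-zero
#'   denominators in rare subsets) or `"mean_of_ratios"`.
#' @param nBoot bootstrap resamples.
#' @param seed bootstrap seed.
#' @param level confidence level.
#' @return Named numeric `c(bias, lo, hi)` in percent.
#' @export
percentBias <- function(pairs, method = c("ratio_of_means", "mean_of_ratios"),
                        nBoot = 2000, seed = 1L, level = 0.95) {
  pairs <- checkPairs(pairs)
  method <- match.arg(method)
  est <- function(h, m) {
    if (method == "ratio_of_means") {
      if (mean(m) <= 0) return(NA_real_)
      100 * (mean(h) - mean(m)) / mean(m)
    } else {
      ok <- m > 0
      if (!any(ok)) return(NA_real_)
      100 * mean(h[ok] / m[ok] - 1)
    }
  }
  bias <- est(pairs$hybrid, pairs$manual)
  if (is.na(bias)) preconditionError("percent bias undefined: mean(manual) is zero")
  n <- nrow(pairs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  boot <- vapply(seq_len(nBoot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    est(pairs$hybrid[idx], pairs$manual[idx])
  }, 0)
  qs <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  c(bias = bias, lo = qs[1], hi = qs[2])
}

#' Signed and absolute mean difference between methods
#'
#' @param pairs data.frame with columns `hybrid`, `manual`.
#' @return Named numeric `c(mean_diff, mean_abs_diff)` in input units
#'   (hybrid minus manual).
#' @export
absoluteDifference <- function(pairs) {
  pairs <- checkPairs(pairs)
  d <- pairs$hybrid - pairs$manual
  c(mean_diff = mean(d), mean_abs_diff = mean(abs(d)))
}

#' Event-level F-measure between two gating methods
#'
#' With the manual mask as truth: `TP = |A & B|`, `FP = |A & !B|`,
#' `FN = |!A & B|` and `F = 2TP / (2TP + FP + FN)`, the harmonic mean of
#' precision and recall. When both masks are empty the degenerate value 1
#' is returned (both methods agree the population is absent).
#'
#' @param maskA logical event mask from the evaluated (hybrid) method.
#' @param maskB logical event mask from the gold-standard (manual) method;
#'   both masks index the same events of the same sample.
#' @return F in \[0, 1\].
#' @export
fMeasure <- function(maskA, maskB) {
  if (length(maskA) != length(maskB))
    preconditionError("membership masks must cover the same events")
  tp <- sum(maskA & maskB)
  fp <- sum(maskA & !maskB)
  fn <- sum(!maskA & maskB)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

#' Remove >3 SD outliers from paired counts
#'
#' Single-pass sensitivity rule: a paired row is removed when either
#' method's value lies more than 3 standard deviations from that method's
#' own mean (no re-iteration after removal).
#'
#' @param pairs data.frame with columns `hybrid`, `manual` (n >= 10).
#' @param k SD multiple.
#' @return List with `pairs` (the filtered rows) and `nRemoved`.
#' @export
removeOutliers <- function(pairs, k = 3) {
  pairs <- checkPairs(pairs)
  if (nrow(pairs) < 10)
    preconditionError("outlier screening needs at least 10 paired samples")
  out <- rep(FALSE, nrow(pairs))
  for (col in c("hybrid", "manual")) {
    v <- pairs[[col]]
    s <- stats::sd(v)
    if (s > 0) out <- out | abs(v - mean(v)) > k * s
  }
  list(pairs = pairs[!out, , drop = FALSE], nRemoved = sum(out))
}

#' Optimization gate on the hybrid/manual correlation
#'
#' A hierarchical gate whose correlation against manual gating exceeds
#' 0.75 is accepted for roll-out; r <= 0.75 is a failure of the automated
#' analysis and sends the population back to iterative refinement.
#'
#' @param r Pearson correlation (finite).
#' @param threshold strict pass threshold.
#' @return `TRUE` (pass) iff r exceeds the threshold strictly.
#' @export
optimizationGate <- function(r, threshold = 0.75) {
  if (!is.finite(r)) preconditionError("optimization gate requires a finite r")
  r > threshold
}
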