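# Concurrent validity of the test device against the criterion: the Linear
# Fit Method (OLS of the test waveform on the criterion waveform, summarized
# by slope alpha1, intercept alpha0 and r^2) on time-normalized cycles, and
# Bland-Altman agreement statistics on cycle-averaged range values.

#' Linear Fit Method for waveform agreement
#'
#' Ordinary least squares of the test waveform on the criterion waveform.
#' Identical waveforms give alpha1 = 1, alpha0 = 0, r^2 = 1; alpha1 is the
#' mean variation of the test waveform per unit change of the criterion,
#' alpha0 the test value when the criterion is 0, and r^2 the squared
#' Pearson correlation.
#'
#' @param test,criterion numeric vectors of equal length >= 3 (typically
#'   concatenated or averaged 101-point normalized cycles).
#' @return object of class `lfm_result` with `alpha1`, `alpha0`, `r2`,
#'   `n_points` and the validity `class` from [classify_r2()].
#' @export
linear_fit_method <- function(test, criterion) {
  if (length(test) != length(criterion)) {
    stop_named("imuagree_precondition", "waveform length mismatch (%d vs %d)",
               length(test), length(criterion))
  }
  if (length(test) < 3) {
    stop_named("imuagree_precondition", "need at least 3 points")
  }
  assert_finite(test, "test waveform"); assert_finite(criterion, "criterion waveform")
  vc <- stats::var(criterion)
  if (vc == 0) {
    stop_named("imuagree_degenerate", "criterion waveform is constant; fit undefined")
  }
  alpha1 <- stats::cov(test, criterion) / vc
  alpha0 <- mean(test) - alpha1 * mean(criterion)
  r2 <- if (stats::var(test) == 0) 0 else stats::cor(test, criterion)^2
  structure(list(alpha1 = alpha1, alpha0 = alpha0, r2 = r2,
                 n_points = length(test), class = classify_r2(r2)),
            class = "lfm_result")
}

#' @export
print.lfm_result <- function(x, ...) {
  cat(sprintf("<lfm_result> alpha1 = %.4f, alpha0 = %.4f, r2 = %.4f (%s), n = %d\n",
              x$alpha1, x$alpha0, x$r2, x$class, x$n_points))
  invisible(x)
}

#' Classify concurrent validity from r-squared
#'
#' r^2 >= 0.75 is excellent, 0.40 <= r^2 < 0.75 fair to good, r^2 < 0.40
#' poor (the bands are half-open so classification is total).
#'
#' @param r2 squared correlation in `[0, 1]`.
#' @return `"excellent"`, `"fair_to_good"` or `"poor"`.
#' @export
classify_r2 <- function(r2) {
  if (!is.finite(r2) || r2 < -1e-12 || r2 > 1 + 1e-12) {
    stop_named("imuagree_precondition", "r2 must lie in [0, 1], got %g", r2)
  }
  if (r2 >= 0.75) "excellent" else if (r2 >= 0.40) "fair_to_good" else "poor"
}

#' Per-participant Linear Fit Method over normalized cycles
#'
#' Pairs test and criterion cycles by cycle index (truncating to the common
#' count) and fits one LFM per participant on either the concatenated cycles
#' (default; uses all data) or the per-participant mean cycle.
#'
#' @param test_cycles,criterion_cycles 101 x m matrices of normalized cycles
#'   for one participant/case.
#' @param mode `"concat"` or `"mean"`.
#' @return an `lfm_result`.
#' @export
lfm_participant <- function(test_cycles, criterion_cycles,
                            mode = c("concat", "mean")) {
  mode <- match.arg(mode)
  m <- min(ncol(test_cycles), ncol(criterion_cycles))
  if (m < 1) stop_named("imuagree_precondition", "no paired cycles")
  tc <- test_cycles[, seq_len(m), drop = FALSE]
  cc <- criterion_cycles[, seq_len(m), drop = FALSE]
  if (mode == "concat") {
    linear_fit_method(as.numeric(tc), as.numeric(cc))
  } else {
    linear_fit_method(rowMeans(tc), rowMeans(cc))
  }
}

#' Summarize per-participant LFM results
#'
#' @param results list of `lfm_result` objects (one per participant).
#' @return one-row data frame with mean and SD of alpha1, alpha0 and r2
#'   across participants, the participant count, and the validity class of
#'   the mean r2.
#' @export
lfm_summary <- function(results) {
  if (!length(results)) stop_named("imuagree_precondition", "empty result list")
  g <- function(f) vapply(results, `[[`, numeric(1), f)
  a1 <- g("alpha1"); a0 <- g("alpha0"); r2 <- g("r2")
  data.frame(alpha1_mean = mean(a1), alpha1_sd = stats::sd(a1),
             alpha0_mean = mean(a0), alpha0_sd = stats::sd(a0),
             r2_mean = mean(r2), r2_sd = stats::sd(r2),
             n_participants = length(results),
             class = classify_r2(min(max(mean(r2), 0), 1)))
}

#' Bland-Altman agreement statistics
#'
#' Differences are taken as criterion - test per pair. Reports the mean
#' difference, its SD, the 95% limits of agreement (mean +/- 1.96 SD), and
#' the t-based 95% confidence interval of the mean difference; pairwise
#' means are returned as the x-coordinates for plotting.
#'
#' @param test,criterion paired numeric vectors, n >= 2 (typically one range
#'   value per participant).
#' @return object of class `bland_altman_result`.
#' @export
bland_altman <- function(test, criterion) {
  if (length(test) != length(criterion)) {
    stop_named("imuagree_precondition", "length mismatch (%d vs %d)",
               length(test), length(criterion))
  }
  n <- length(test)
  if (n < 2) stop_named("imuagree_precondition", "need n >= 2 pairs")
  d <- criterion - test
  m <- mean(d); s <- stats::sd(d)
  tcrit <- stats::qt(0.975, n - 1)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 ci95_mean_diff = c(m - tcrit * s / sqrt(n), m + tcrit * s / sqrt(n)),
                 means = (test + criterion) / 2, diffs = d, n = n),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman> mean diff %.4f [LoA %.4f, %.4f; 95%% CI %.4f, %.4f], n = %d\n",
              x$mean_diff, x$loa_lower, x$loa_upper,
              x$ci95_mean_diff[1], x$ci95_mean_diff[2], x$n))
  invisible(x)
}
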