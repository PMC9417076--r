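# Test-retest reliability: two-way random-effects consistency intraclass
# correlation ICC(C,1) computed from the two-way ANOVA mean squares, its
# F-based 95% confidence interval, the standard error of measurement
# SEM = SD * sqrt(1 - ICC), classification bands, and the
# Walter-Eliasziw-Donner sample-size procedure for reliability studies.

#' Two-way random-effects consistency ICC
#'
#' ICC(C,1) (McGraw-Wong) from the subjects x sessions matrix:
#' `(MS_rows - MS_error) / (MS_rows + (k - 1) MS_error)` with the session
#' (column) effect removed, so fixed between-session offsets do not lower
#' the coefficient. The 95% CI is the standard F-based interval. With
#' `form = "average"` the ICC(C,k) of session means is returned instead.
#'
#' @param data complete numeric matrix, subjects in rows (n >= 2), sessions
#'   in columns (k >= 2).
#' @param conf confidence level (default 0.95).
#' @param form `"single"` (default, ICC(C,1)) or `"average"` (ICC(C,k)).
#' @return object of class `icc_result` with `icc`, `ci95`, `model`,
#'   `class` ([classify_icc()]), `n_subjects`, `k_sessions`, and the ANOVA
#'   mean squares `ms_rows`, `ms_error`.
#' @export
icc_consistency <- function(data, conf = 0.95, form = c("single", "average")) {
  form <- match.arg(form)
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) {
    stop_named("imuagree_precondition", "need >= 2 subjects and >= 2 sessions")
  }
  if (!all(is.finite(data))) {
    stop_named("imuagree_precondition", "matrix must be complete and finite")
  }
  grand <- mean(data)
  if (sum((data - grand)^2) == 0) {
    stop_named("imuagree_degenerate", "zero total variance; ICC undefined")
  }
  row_m <- rowMeans(data); col_m <- colMeans(data)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot  <- sum((data - grand)^2)
  ss_err  <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err  <- ss_err / ((n - 1) * (k - 1))

  if (ms_err == 0) {
    icc <- 1; ci <- c(1, 1)
  } else {
    icc <- (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
    f <- ms_rows / ms_err
    a <- (1 - conf) / 2
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- f / stats::qf(1 - a, df1, df2)
    fu <- f * stats::qf(1 - a, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    if (form == "average") {
      icc <- (ms_rows - ms_err) / ms_rows
      ci <- c((fl - 1) / fl, (fu - 1) / fu)
    }
  }
  structure(list(
    icc = icc, ci95 = ci,
    model = sprintf("two-way random, consistency, %s measures",
                    if (form == "single") "single" else "average"),
    class = classify_icc(icc), n_subjects = n, k_sessions = k,
    ms_rows = ms_rows, ms_error = ms_err
  ), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.3f [%.3f, %.3f] (%s; %s), n = %d, k = %d\n",
              x$icc, x$ci95[1], x$ci95[2], x$class, x$model,
              x$n_subjects, x$k_sessions))
  invisible(x)
}

#' Standard error of measurement from an ICC
#'
#' `SEM = SD * sqrt(1 - ICC)`, where SD is the standard deviation, across
#' participants, of each participant's mean of the compared measurements.
#'
#' @param sd standard deviation of the outcome (>= 0).
#' @param icc intraclass correlation (<= 1; negative estimates allowed).
#' @return SEM in the outcome's units.
#' @export
sem_from_icc <- function(sd, icc) {
  stopifnot(sd >= 0)
  if (icc > 1) stop_named("imuagree_precondition", "icc must be <= 1")
  sd * sqrt(1 - icc)
}

#' Classify test-retest reliability from an ICC
#'
#' ICC >= 0.75 is excellent, 0.40 <= ICC < 0.75 fair-to-high, anything
#' below 0.40 (including negative estimates) poor.
#'
#' @param icc intraclass correlation (<= 1).
#' @return `"excellent"`, `"fair_to_high"` or `"poor"`.
#' @export
classify_icc <- function(icc) {
  if (icc > 1 + 1e-12) stop_named("imuagree_precondition", "icc must be <= 1")
  if (icc >= 0.75) "excellent" else if (icc >= 0.40) "fair_to_high" else "poor"
}

#' Count and percentage of cases per classification
#'
#' Summarizes a set of case classifications (e.g. one per location x axis x
#' activity cell) as counts and percentages, rounded half-up to one decimal
#' (so 1 of 45 is 2.2% and 7 of 45 is 15.6%).
#'
#' @param classes character vector of class labels, or a list of
#'   `icc_result`/`lfm_result` objects.
#' @param levels label set defining the row order; defaults to the union of
#'   reliability and validity bands present.
#' @return data frame with `class`, `count`, `pct`.
#' @export
classification_summary <- function(classes, levels = NULL) {
  if (is.list(classes)) {
    classes <- vapply(classes, function(r) r$class, character(1))
  }
  if (!length(classes)) stop_named("imuagree_precondition", "empty input")
  levels <- levels %||% intersect(
    c("excellent", "fair_to_high", "fair_to_good", "poor"), unique(classes))
  counts <- vapply(levels, function(l) sum(classes == l), integer(1))
  data.frame(class = levels, count = counts,
             pct = round_half_up(100 * counts / length(classes), 1),
             row.names = NULL)
}

# 1 + k * rho / (1 - rho): scale factor of the one-way F statistic
icc_f_scale <- function(rho, k) (1 + (k - 1) * rho) / (1 - rho)

#' Sample size for a reliability study (Walter-Eliasziw-Donner)
#'
#' Number of subjects needed to test H0: rho = rho0 (minimally acceptable
#' reliability) against H1: rho = rho1 (expected reliability) with k
#' observations per subject, significance alpha and power 1 - beta.
#' `method = "approx"` uses the ln-transform approximation
#' `n = 2 + 2 k (z_a + z_b)^2 / ((k - 1) (ln C0)^2)` with
#' `C0 = [(1 + (k-1) rho0)/(1 - rho0)] / [(1 + (k-1) rho1)/(1 - rho1)]`;
#' `method = "exact"` searches for the smallest n whose one-sided F-test of
#' the intraclass correlation reaches the target power.
#'
#' @param alpha significance level (one-sided by default).
#' @param beta type II error rate.
#' @param k observations (sessions) per subject, >= 2.
#' @param rho0,rho1 null and alternative reliability, `0 <= rho0 < rho1 < 1`.
#' @param method `"exact"` (default) or `"approx"`.
#' @param two_sided if `TRUE`, alpha is split two-sided (`alpha/2`).
#' @return required number of subjects (integer, rounded up), with the
#'   achieved power at that n as attribute `"power"` for the exact method.
#' @export
reliability_sample_size <- function(alpha = 0.05, beta = 0.2, k, rho0, rho1,
                                    method = c("exact", "approx"),
                                    two_sided = FALSE) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1, k >= 2)
  if (!(rho0 >= 0 && rho0 < rho1 && rho1 < 1)) {
    stop_named("imuagree_precondition", "need 0 <= rho0 < rho1 < 1")
  }
  a <- if (two_sided) alpha / 2 else alpha
  c0 <- icc_f_scale(rho0, k) / icc_f_scale(rho1, k)
  if (method == "approx") {
    za <- stats::qnorm(1 - a); zb <- stats::qnorm(1 - beta)
    return(as.integer(ceiling(2 + 2 * k * (za + zb)^2 / ((k - 1) * log(c0)^2))))
  }
  for (n in 2:100000) {
    pow <- icc_test_power(n, k, rho0, rho1, a)
    if (pow >= 1 - beta) {
      return(structure(as.integer(n), power = pow))
    }
  }
  stop_named("imuagree_degenerate", "no feasible n found")
}

#' Power of the one-sided F-test of an intraclass correlation
#'
#' Probability of rejecting H0: rho = rho0 at level `alpha` when the true
#' reliability is rho1, with n subjects and k observations each (one-way
#' random-effects F statistic).
#'
#' @param n subjects; @param k observations per subject.
#' @param rho0,rho1 null and true reliability.
#' @param alpha one-sided significance level.
#' @return power in `[0, 1]`.
#' @export
icc_test_power <- function(n, k, rho0, rho1, alpha = 0.05) {
  df1 <- n - 1; df2 <- n * (k - 1)
  crit <- (icc_f_scale(rho0, k) / icc_f_scale(rho1, k)) *
    stats::qf(1 - alpha, df1, df2)
  1 - stats::pf(crit, df1, df2)
}
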