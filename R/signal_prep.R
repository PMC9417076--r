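# Signal conditioning: zero-phase low-pass Butterworth filtering and
# direction inversion for walking trials. The filter is applied forward and
# backward (dual pass), so the effective magnitude response is the square of
# the single-pass design and the phase response is zero -- phase lag would
# desynchronize test and criterion waveforms and bias the Linear Fit Method.

#' Zero-phase low-pass Butterworth filter
#'
#' Designs a digital Butterworth low-pass filter (bilinear transform, as in
#' MATLAB's `butter`) and applies it forward and backward. The signal mean is
#' removed before filtering and restored afterwards, and the signal is
#' extended by odd reflection at both ends before the dual pass, so constant
#' signals pass through exactly and edge transients are suppressed.
#'
#' @param x numeric signal, length > 6 x `order`.
#' @param sample_rate sampling rate in Hz.
#' @param cutoff low-pass cutoff in Hz (default 6); must be below Nyquist.
#' @param order filter order of the single pass (default 2).
#' @return filtered signal, same length as `x`; DC gain exactly 1.
#' @export
lowpass_filter <- function(x, sample_rate, cutoff = 6, order = 2) {
  n <- length(x)
  if (n <= 6 * order) {
    stop_named("imuagree_precondition",
               "signal too short for filtering: need length > %d, got %d",
               6 * order, n)
  }
  assert_finite(x, "signal")
  if (cutoff >= sample_rate / 2) {
    stop_named("imuagree_precondition",
               "cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff, sample_rate / 2)
  }
  ba <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  mu <- mean(x)
  xc <- x - mu
  pad <- min(n - 1L, max(12L, 5L * ceiling(sample_rate / cutoff)))
  front <- 2 * xc[1] - xc[(pad + 1):2]
  back  <- 2 * xc[n] - xc[(n - 1):(n - pad)]
  xp <- c(front, xc, back)
  yp <- signal::filter(ba$b, ba$a, xp)
  yp <- rev(signal::filter(ba$b, ba$a, rev(yp)))
  as.numeric(yp[(pad + 1):(pad + n)]) + mu
}

#' Magnitude response of the low-pass filter
#'
#' Numerically evaluates |H(e^{i 2 pi f / fs})|^passes for the digital
#' Butterworth design used by [lowpass_filter()]. With `passes = 2` this is
#' the effective amplitude gain of the zero-phase dual-pass application.
#'
#' @param freq frequency (Hz) at which to evaluate, vectorized.
#' @param sample_rate sampling rate in Hz.
#' @param cutoff cutoff in Hz.
#' @param order filter order of the single pass.
#' @param passes 1 for a single pass, 2 (default) for the dual pass.
#' @return amplitude gain(s) in (0, 1].
#' @export
filter_response <- function(freq, sample_rate, cutoff = 6, order = 2, passes = 2) {
  ba <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  vapply(freq, function(f) {
    zi <- exp(1i * 2 * pi * f / sample_rate)
    h <- sum(ba$b * zi^-(seq_along(ba$b) - 1)) / sum(ba$a * zi^-(seq_along(ba$a) - 1))
    Mod(h)^passes
  }, numeric(1))
}

#' Invert a signal according to walking-direction flags
#'
#' Walking trials are performed back and forth; the x and y acceleration axes
#' change sign with walking direction and are multiplied by the per-sample
#' direction flag so that all strides share one sign convention.
#'
#' @param x numeric signal.
#' @param flags numeric vector of +1/-1, same length as `x`.
#' @return samplewise product `x * flags`.
#' @export
invert_for_direction <- function(x, flags) {
  if (length(flags) != length(x)) {
    stop_named("imuagree_precondition",
               "direction flags length (%d) != signal length (%d)",
               length(flags), length(x))
  }
  if (!all(flags %in% c(-1, 1))) {
    stop_named("imuagree_precondition", "direction flags must be +1 or -1")
  }
  x * flags
}
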