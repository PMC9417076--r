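# Movement-cycle segmentation and per-cycle outcomes. For every activity a
# cycle runs from a local maximum of the thigh-orientation x-angle, through
# the dominant trough, to the next local maximum; the first and last cycle of
# each trial are discarded, the remainder are linearly interpolated onto a
# 0-100% grid of 101 points, and each cycle is summarized by its range
# (max - min). All sample indices are 1-based.

local_extrema <- function(x, kind = c("max", "min")) {
  kind <- match.arg(kind)
  if (kind == "min") x <- -x
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

# topographic prominence of the trough at index i (on the inverted signal)
trough_prominence <- function(x, i) {
  v <- x[i]
  n <- length(x)
  left <- if (i > 1) {
    lower <- which(x[1:(i - 1)] < v)
    from <- if (length(lower)) max(lower) + 1L else 1L
    max(x[from:(i - 1)])
  } else -Inf
  right <- if (i < n) {
    lower <- which(x[(i + 1):n] < v) + i
    to <- if (length(lower)) min(lower) - 1L else n
    max(x[(i + 1):to])
  } else -Inf
  bases <- c(left, right)
  bases <- bases[is.finite(bases)]
  if (!length(bases)) return(0)
  min(bases) - v
}

#' Detect movement cycles from the thigh-orientation x-angle
#'
#' Qualifying troughs are local minima whose prominence reaches
#' `prominence_floor` and that are separated from deeper qualifying troughs
#' by at least `min_period`. Each trough is flanked by its nearest preceding
#' and succeeding local maximum; troughs missing a flank (signal edges) are
#' omitted.
#'
#' @param thigh_ori_x filtered thigh-orientation x-angle signal (degrees).
#' @param sample_rate sampling rate in Hz.
#' @param min_period minimum separation between troughs in seconds
#'   (default 0.5).
#' @param prominence_floor minimum trough prominence in degrees; defaults to
#'   25% of the signal's own amplitude range.
#' @return `cycle_boundaries`: data frame with integer columns `start`,
#'   `trough`, `end` (1-based sample indices, strictly increasing; adjacent
#'   cycles share boundary maxima). Zero qualifying troughs yield an empty
#'   frame, not an error.
#' @export
detect_cycles <- function(thigh_ori_x, sample_rate, min_period = 0.5,
                          prominence_floor = NULL) {
  assert_finite(thigh_ori_x, "thigh orientation signal")
  stopifnot(min_period > 0, sample_rate > 0)
  x <- as.numeric(thigh_ori_x)
  if (is.null(prominence_floor)) {
    prominence_floor <- 0.25 * diff(range(x))
  }
  empty <- data.frame(start = integer(0), trough = integer(0), end = integer(0))
  class(empty) <- c("cycle_boundaries", "data.frame")
  if (diff(range(x)) == 0) return(empty)

  troughs <- local_extrema(x, "min")
  if (!length(troughs)) return(empty)
  prom <- vapply(troughs, function(i) trough_prominence(x, i), numeric(1))
  troughs <- troughs[prom >= prominence_floor]
  if (!length(troughs)) return(empty)

  # enforce minimum separation, keeping deeper troughs
  min_gap <- min_period * sample_rate
  keep <- integer(0)
  for (i in troughs[order(x[troughs])]) {
    if (!length(keep) || all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  troughs <- sort(keep)

  maxima <- local_extrema(x, "max")
  rows <- lapply(troughs, function(tr) {
    before <- maxima[maxima < tr]
    after  <- maxima[maxima > tr]
    if (!length(before) || !length(after)) return(NULL)
    data.frame(start = max(before), trough = tr, end = min(after))
  })
  out <- do.call(rbind, c(rows, list(empty)))
  class(out) <- c("cycle_boundaries", "data.frame")
  attr(out, "n_troughs") <- length(troughs)
  out
}

#' Discard the first and last movement cycle
#'
#' End cycles are susceptible to initiation/termination transients and are
#' removed before analysis. With two or fewer cycles nothing survives; a
#' warning is raised and an empty boundary set returned.
#'
#' @param b `cycle_boundaries` from [detect_cycles()].
#' @return `cycle_boundaries` with the first and last row removed.
#' @export
discard_end_cycles <- function(b) {
  if (nrow(b) <= 2L) {
    if (nrow(b) > 0L) warning("2 or fewer cycles detected; none retained after end-discard")
    out <- b[integer(0), , drop = FALSE]
  } else {
    out <- b[2:(nrow(b) - 1L), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("cycle_boundaries", "data.frame")
  out
}

#' Segment a signal at cycle boundaries and time-normalize each cycle
#'
#' Each segment `start:end` is interpolated onto 101 equally spaced points
#' (0, 1, ..., 100% of the cycle, endpoints included).
#'
#' @param x numeric signal; all streams of a trial are cut with the
#'   boundaries derived from that trial's own thigh-orientation signal.
#' @param b `cycle_boundaries`.
#' @param n_points grid size (default 101).
#' @param method `"linear"` (default) or `"spline"` interpolation.
#' @return `n_points` x `nrow(b)` matrix, one column per cycle.
#' @export
segment_and_normalize <- function(x, b, n_points = 101L,
                                  method = c("linear", "spline")) {
  method <- match.arg(method)
  if (nrow(b) && (min(b$start) < 1L || max(b$end) > length(x))) {
    stop_named("imuagree_precondition", "cycle boundary outside signal range")
  }
  out <- matrix(NA_real_, nrow = n_points, ncol = nrow(b))
  grid <- seq(0, 1, length.out = n_points)
  for (j in seq_len(nrow(b))) {
    seg <- x[b$start[j]:b$end[j]]
    s <- seq(0, 1, length.out = length(seg))
    out[, j] <- if (method == "linear") {
      stats::approx(s, seg, xout = grid)$y
    } else {
      stats::spline(s, seg, xout = grid)$y
    }
  }
  out
}

#' Range of a time-normalized cycle
#'
#' @param cycle numeric vector (one normalized cycle).
#' @return `max - min`, always >= 0.
#' @export
cycle_range <- function(cycle) {
  assert_finite(cycle, "cycle")
  max(cycle) - min(cycle)
}

#' Euclidean norm of a 3-axis acceleration cycle triplet
#'
#' Combines the per-axis cycles of one segment into the axis-independent
#' acceleration magnitude, samplewise sqrt(z^2 + x^2 + y^2).
#'
#' @param z,x,y numeric vectors or matrices of identical dimensions (columns
#'   = cycles from the same segments).
#' @return object of the same shape with the samplewise norm.
#' @export
euclidean_norm <- function(z, x, y) {
  if (!identical(dim(z) %||% length(z), dim(x) %||% length(x)) ||
      !identical(dim(z) %||% length(z), dim(y) %||% length(y))) {
    stop_named("imuagree_precondition", "axis cycles have mismatched dimensions")
  }
  sqrt(z^2 + x^2 + y^2)
}

#' Aggregate per-cycle ranges into a participant-level range table
#'
#' Per (participant, device, session, activity, location, quantity, axis)
#' the per-cycle ranges are averaged and the number of cycles recorded.
#' Groups with zero retained cycles are omitted with a warning.
#'
#' @param cycle_ranges long data frame with columns `participant`, `device`,
#'   `session`, `activity`, `location`, `quantity`, `axis`, `cycle`, `range`.
#' @return range table data frame (see [write_long_table()] for the schema).
#' @export
aggregate_ranges <- function(cycle_ranges) {
  if (!nrow(cycle_ranges)) {
    warning("no cycles to aggregate")
    return(as.data.frame(setNames(rep(list(character(0)), length(RANGE_TABLE_COLS)),
                                  RANGE_TABLE_COLS)))
  }
  keys <- c("participant", "device", "session", "activity", "location",
            "quantity", "axis")
  agg <- stats::aggregate(cycle_ranges["range"], cycle_ranges[keys], function(v) {
    c(mean = mean(v), n = length(v))
  })
  out <- agg[keys]
  out$range_value <- agg$range[, "mean"]
  out$n_cycles_used <- as.integer(agg$range[, "n"])
  out[do.call(order, out[keys]), , drop = FALSE]
}

#' Cohort-level mean ranges
#'
#' Averages participant means over participants (never pooling cycles), per
#' (device, session, activity, location, quantity, axis).
#'
#' @param range_table participant-level table from [aggregate_ranges()].
#' @return data frame with `mean_range`, `sd_range` and `n_participants` per
#'   case.
#' @export
cohort_mean_ranges <- function(range_table) {
  keys <- c("device", "session", "activity", "location", "quantity", "axis")
  agg <- stats::aggregate(range_table["range_value"], range_table[keys], function(v) {
    c(mean = mean(v), sd = stats::sd(v), n = length(v))
  })
  out <- agg[keys]
  out$mean_range <- agg$range_value[, "mean"]
  out$sd_range <- agg$range_value[, "sd"]
  out$n_participants <- as.integer(agg$range_value[, "n"])
  out
}
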