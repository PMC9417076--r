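# On-disk dialects: one canonical CSV schema for per-sensor recordings, a
# YAML trial manifest, and a long-format CSV for range outcomes. All numeric
# output is printed with 15 significant digits so read/write round-trips are
# exact to well below 1e-9.

REC_NUM_COLS <- c("time",
                  "quat_w", "quat_x", "quat_y", "quat_z",
                  "freeacc_z", "freeacc_x", "freeacc_y")

RANGE_TABLE_COLS <- c("participant", "device", "session", "activity",
                      "location", "quantity", "axis",
                      "range_value", "n_cycles_used")

#' Construct a sensor recording
#'
#' One device x location x session x activity stream of orientation
#' quaternions and free accelerations sampled at a constant rate.
#'
#' @param participant participant identifier (character).
#' @param device `"test"` or `"criterion"`.
#' @param location `"sacrum"`, `"thigh"` or `"shank"`.
#' @param session session number, 1-3.
#' @param activity one of `squat`, `jump`, `walk`, `stair_ascent`,
#'   `stair_descent`.
#' @param quat n x 4 matrix of unit quaternions (w, x, y, z).
#' @param free_acc n x 3 matrix of free accelerations in m/s^2, axis order
#'   (z, x, y).
#' @param sample_rate sampling rate in Hz (default 60).
#' @param side body side: `"left"`, `"right"` or `"none"`; defaults to
#'   `"none"` for the sacrum and `"right"` otherwise.
#' @param walk_direction per-sample direction flags (+1/-1); required for
#'   walking trials and disallowed otherwise.
#' @return an object of class `sensor_recording`.
#' @export
sensor_recording <- function(participant, device, location, session, activity,
                             quat, free_acc, sample_rate = 60,
                             side = if (location == "sacrum") "none" else "right",
                             walk_direction = NULL) {
  device   <- match.arg(device, DEVICES)
  location <- match.arg(location, LOCATIONS)
  activity <- match.arg(activity, ACTIVITIES)
  side     <- match.arg(side, c("left", "right", "none"))
  quat <- as.matrix(quat); free_acc <- as.matrix(free_acc)
  rec <- structure(list(
    participant = as.character(participant), device = device,
    location = location, side = side, session = as.integer(session),
    activity = activity, sample_rate = sample_rate,
    quat = quat, free_acc = free_acc, walk_direction = walk_direction
  ), class = "sensor_recording")
  validate_recording(rec)
}

#' Validate a sensor recording's invariants
#'
#' @param rec a `sensor_recording`.
#' @return `rec`, invisibly usable, after checking stream lengths, quaternion
#'   norms (within 1e-6 of 1), positive sample rate, and the presence of
#'   walk-direction flags exactly for walking trials.
#' @export
validate_recording <- function(rec) {
  n <- nrow(rec$quat)
  if (is.null(n) || n < 2L) {
    stop_named("imuagree_precondition", "recording must have at least 2 samples")
  }
  if (ncol(rec$quat) != 4L || ncol(rec$free_acc) != 3L || nrow(rec$free_acc) != n) {
    stop_named("imuagree_precondition",
               "quat must be n x 4 and free_acc n x 3 with equal n")
  }
  assert_finite(rec$quat, "quat")
  assert_finite(rec$free_acc, "free_acc")
  if (any(abs(quat_norms(rec$quat) - 1) > 1e-6)) {
    stop_named("imuagree_integrity", "quaternion norms deviate from 1 by > 1e-6")
  }
  if (!is.numeric(rec$sample_rate) || rec$sample_rate <= 0) {
    stop_named("imuagree_precondition", "sample_rate must be > 0")
  }
  if (!(rec$session %in% 1:3)) {
    stop_named("imuagree_precondition", "session must be 1, 2 or 3")
  }
  has_dir <- !is.null(rec$walk_direction)
  if (has_dir != (rec$activity == "walk")) {
    stop_named("imuagree_precondition",
               "walk_direction must be present iff activity == 'walk'")
  }
  if (has_dir) {
    if (length(rec$walk_direction) != n || !all(rec$walk_direction %in% c(-1, 1))) {
      stop_named("imuagree_precondition",
                 "walk_direction must be +1/-1 flags of the stream length")
    }
  }
  rec
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %s %s %s (side %s), session %d, %s: %d samples @ %g Hz\n",
              x$participant, x$device, x$location, x$side, x$session,
              x$activity, nrow(x$quat), x$sample_rate))
  invisible(x)
}

#' Read a sensor recording from its canonical CSV
#'
#' The dialect has columns `time`, `quat_w`, `quat_x`, `quat_y`, `quat_z`,
#' `freeacc_z`, `freeacc_x`, `freeacc_y`, plus `direction` (+1/-1) for
#' walking trials. Samples are kept in file order; quaternions whose norm
#' deviates from 1 by at most 1e-3 are renormalized, larger deviations are
#' an integrity error.
#'
#' @param path CSV file path.
#' @param meta named list with `participant`, `device`, `location`, `session`,
#'   `activity` (and optionally `side`) copied onto the recording.
#' @return a [sensor_recording()].
#' @export
read_recording <- function(path, meta) {
  if (!file.exists(path)) {
    stop_named("imuagree_io", "file not found: %s", path)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(REC_NUM_COLS, names(df))
  if (length(missing)) {
    stop_named("imuagree_format", "missing column(s): %s",
               paste(missing, collapse = ", "))
  }
  num <- as.matrix(df[REC_NUM_COLS])
  if (!all(is.finite(num))) {
    bad <- which(!apply(is.finite(num), 1, all))[1]
    stop_named("imuagree_parse", "non-finite value at data row %d of %s", bad, path)
  }
  quat <- num[, c("quat_w", "quat_x", "quat_y", "quat_z"), drop = FALSE]
  nrm <- quat_norms(quat)
  if (any(abs(nrm - 1) > 1e-3)) {
    stop_named("imuagree_integrity",
               "quaternion norm deviates from 1 by > 1e-3 (max %.3g) in %s",
               max(abs(nrm - 1)), path)
  }
  quat <- quat / nrm
  dir <- NULL
  if (identical(meta$activity, "walk")) {
    if (!"direction" %in% names(df)) {
      stop_named("imuagree_format", "missing column(s): direction (walking trial)")
    }
    dir <- df$direction
  }
  sample_rate <- meta$sample_rate %||% {
    if (nrow(num) > 1) 1 / stats::median(diff(num[, "time"])) else 60
  }
  sensor_recording(
    participant = meta$participant, device = meta$device,
    location = meta$location, session = meta$session, activity = meta$activity,
    quat = quat,
    free_acc = num[, c("freeacc_z", "freeacc_x", "freeacc_y"), drop = FALSE],
    sample_rate = round(sample_rate, 6),
    side = meta$side %||% if (meta$location == "sacrum") "none" else "right",
    walk_direction = dir
  )
}

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

#' Write a sensor recording to its canonical CSV
#'
#' Numbers are printed with 15 significant digits; a read/write round trip
#' preserves every field to well below 1e-9.
#'
#' @param rec a valid [sensor_recording()] (length >= 2; empty recordings are
#'   rejected by construction).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  n <- nrow(rec$quat)
  df <- data.frame(
    time = fmt_num((seq_len(n) - 1) / rec$sample_rate),
    quat_w = fmt_num(rec$quat[, 1]), quat_x = fmt_num(rec$quat[, 2]),
    quat_y = fmt_num(rec$quat[, 3]), quat_z = fmt_num(rec$quat[, 4]),
    freeacc_z = fmt_num(rec$free_acc[, 1]),
    freeacc_x = fmt_num(rec$free_acc[, 2]),
    freeacc_y = fmt_num(rec$free_acc[, 3]),
    check.names = FALSE
  )
  if (!is.null(rec$walk_direction)) df$direction <- rec$walk_direction
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a long-format range table to CSV
#'
#' One row per (participant, device, session, activity, location, axis) with
#' the cycle-averaged range value and the number of cycles used. Column order
#' is fixed.
#'
#' @param rows data frame with the [RANGE_TABLE_COLS] schema (extra columns
#'   are an error).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(rows, path) {
  if (nrow(rows) > 0 || ncol(rows) > 0) {
    missing <- setdiff(RANGE_TABLE_COLS, names(rows))
    extra <- setdiff(names(rows), RANGE_TABLE_COLS)
    if (length(missing) || length(extra)) {
      stop_named("imuagree_format",
                 "schema mismatch: missing [%s], unexpected [%s]",
                 paste(missing, collapse = ", "), paste(extra, collapse = ", "))
    }
    rows <- rows[RANGE_TABLE_COLS]
    rows$range_value <- fmt_num(rows$range_value)
  } else {
    rows <- as.data.frame(setNames(rep(list(character(0)), length(RANGE_TABLE_COLS)),
                                   RANGE_TABLE_COLS))
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format range table written by [write_long_table()]
#'
#' @param path CSV path.
#' @return data frame with the fixed schema.
#' @export
read_long_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(participant = "character"))
  missing <- setdiff(RANGE_TABLE_COLS, names(df))
  if (length(missing)) {
    stop_named("imuagree_format", "missing column(s): %s",
               paste(missing, collapse = ", "))
  }
  df
}

#' Write a trial manifest to YAML
#'
#' @param manifest list with elements `sample_rate` and `trials` (data frame
#'   with columns participant, session, activity, device, location, path) and
#'   optionally `direction_spans`, a named list keyed
#'   `"participant|session|activity"` of data frames (start, end, flag) giving
#'   1-based inclusive sample spans of walking direction.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  tr <- manifest$trials
  out <- list(
    sample_rate = manifest$sample_rate %||% 60,
    trials = lapply(seq_len(nrow(tr)), function(i) {
      as.list(tr[i, c("participant", "session", "activity", "device",
                      "location", "path")])
    }),
    direction_spans = lapply(manifest$direction_spans %||% list(), function(d) {
      lapply(seq_len(nrow(d)), function(i) as.list(d[i, c("start", "end", "flag")]))
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a trial manifest from YAML
#'
#' Validates that (participant, session, activity, device, location) keys are
#' unique and, optionally, that every referenced file exists.
#'
#' @param path YAML path written by [write_manifest()].
#' @param check_files verify that every referenced recording file exists
#'   (default `TRUE`).
#' @return manifest list (see [write_manifest()]); relative paths are resolved
#'   against the manifest's directory.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  raw <- yaml::read_yaml(path)
  tr <- do.call(rbind, lapply(raw$trials, function(t) {
    data.frame(participant = as.character(t$participant),
               session = as.integer(t$session), activity = t$activity,
               device = t$device, location = t$location, path = t$path)
  }))
  key <- do.call(paste, tr[c("participant", "session", "activity", "device", "location")])
  if (anyDuplicated(key)) {
    stop_named("imuagree_integrity", "duplicate trial keys in manifest")
  }
  base <- dirname(path)
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", tr$path), tr$path, file.path(base, tr$path))
  if (check_files && !all(file.exists(abs))) {
    stop_named("imuagree_io", "manifest references missing file(s): %s",
               paste(utils::head(abs[!file.exists(abs)], 3), collapse = ", "))
  }
  tr$path <- abs
  spans <- lapply(raw$direction_spans %||% list(), function(d) {
    do.call(rbind, lapply(d, function(s) {
      data.frame(start = as.integer(s$start), end = as.integer(s$end),
                 flag = as.numeric(s$flag))
    }))
  })
  list(sample_rate = raw$sample_rate %||% 60, trials = tr, direction_spans = spans)
}

# expand per-trial direction spans into per-sample flags
spans_to_flags <- function(spans, n) {
  flags <- rep(1, n)
  if (is.null(spans)) return(flags)
  for (i in seq_len(nrow(spans))) {
    flags[spans$start[i]:min(spans$end[i], n)] <- spans$flag[i]
  }
  flags
}
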