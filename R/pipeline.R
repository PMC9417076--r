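# Orchestration: raw recordings -> conditioned streams -> cycles -> range
# table -> validity / reliability reports. The case grid mirrors the study
# design: 3 locations x 3 axes x 5 activities = 45 cases per quantity
# (acceleration, orientation), plus 15 acceleration Euclidean-norm cases.

#' Pipeline configuration
#'
#' @param filter_cutoff low-pass cutoff in Hz (default 6).
#' @param filter_order Butterworth order of the single pass (default 2).
#' @param filter_before_euler if `TRUE`, quaternion components are filtered
#'   before Euler conversion instead of the Euler angles after (default
#'   `FALSE`: convert, unwrap, then filter).
#' @param min_period minimum trough separation in seconds (default 0.5).
#' @param prominence_frac trough prominence floor as a fraction of the
#'   signal's amplitude range (default 0.25).
#' @param interp cycle interpolation, `"linear"` (default) or `"spline"`.
#' @param lfm_mode per-participant LFM on `"concat"`enated cycles (default)
#'   or the `"mean"` cycle.
#' @param icc_form `"single"` (default) or `"average"`.
#' @return list of settings.
#' @export
pipeline_config <- function(filter_cutoff = 6, filter_order = 2,
                            filter_before_euler = FALSE,
                            min_period = 0.5, prominence_frac = 0.25,
                            interp = c("linear", "spline"),
                            lfm_mode = c("concat", "mean"),
                            icc_form = c("single", "average")) {
  stopifnot(filter_cutoff > 0, filter_order >= 1, min_period > 0,
            prominence_frac > 0, prominence_frac < 1)
  list(filter_cutoff = filter_cutoff, filter_order = filter_order,
       filter_before_euler = filter_before_euler,
       min_period = min_period, prominence_frac = prominence_frac,
       interp = match.arg(interp), lfm_mode = match.arg(lfm_mode),
       icc_form = match.arg(icc_form))
}

# condition one recording: Euler conversion, filtering, walk inversion.
# returns list of named streams (ori_z/x/y, acc_z/x/y), each a numeric vector
condition_recording <- function(rec, config) {
  fs <- rec$sample_rate
  lp <- function(x) lowpass_filter(x, fs, config$filter_cutoff, config$filter_order)
  if (isTRUE(config$filter_before_euler)) {
    q <- apply(rec$quat, 2, lp)
    q <- q / quat_norms(q)
    eul <- quat_to_euler_zxy(q)
  } else {
    eul <- quat_to_euler_zxy(rec$quat)
    eul <- apply(eul, 2, lp)
  }
  acc <- apply(rec$free_acc, 2, lp)
  colnames(acc) <- AXES
  if (rec$activity == "walk") {
    for (ax in c("x", "y")) {
      acc[, ax] <- invert_for_direction(acc[, ax], rec$walk_direction)
    }
  }
  streams <- list()
  for (ax in AXES) {
    streams[[paste0("ori_", ax)]] <- eul[, ax]
    streams[[paste0("acc_", ax)]] <- acc[, ax]
  }
  streams
}

# process all locations of one (participant, session, activity, device):
# cycles are detected on the device's own thigh-orientation x stream and all
# streams of all locations segmented with those boundaries.
process_device_trial <- function(recs_by_location, config) {
  thigh <- recs_by_location$thigh
  if (is.null(thigh)) {
    stop_named("imuagree_precondition", "trial lacks a thigh recording")
  }
  cond <- lapply(recs_by_location, condition_recording, config = config)
  b <- detect_cycles(cond$thigh$ori_x, thigh$sample_rate,
                     min_period = config$min_period,
                     prominence_floor = config$prominence_frac *
                       diff(range(cond$thigh$ori_x)))
  n_troughs <- attr(b, "n_troughs") %||% nrow(b)
  n_detected <- nrow(b)
  b <- discard_end_cycles(b)
  cycles <- list(); ranges <- list()
  if (nrow(b)) {
    for (loc in names(cond)) {
      segs <- lapply(cond[[loc]], segment_and_normalize, b = b,
                     method = config$interp)
      segs$acc_norm <- euclidean_norm(segs$acc_z, segs$acc_x, segs$acc_y)
      for (nm in names(segs)) {
        qty <- if (nm == "acc_norm") "acc_norm" else sub("_.*", "", nm)
        ax <- if (nm == "acc_norm") "norm" else sub(".*_", "", nm)
        cycles[[paste(loc, qty, ax, sep = "|")]] <- segs[[nm]]
        ranges[[paste(loc, qty, ax, sep = "|")]] <- data.frame(
          location = loc, quantity = qty, axis = ax,
          cycle = seq_len(ncol(segs[[nm]])),
          range = apply(segs[[nm]], 2, cycle_range))
      }
    }
  }
  list(boundaries = b, n_troughs = n_troughs, n_detected = n_detected,
       n_retained = nrow(b),
       cycles = cycles, cycle_ranges = do.call(rbind, c(ranges, list(
         data.frame(location = character(0), quantity = character(0),
                    axis = character(0), cycle = integer(0),
                    range = numeric(0))))))
}

load_cohort_recordings <- function(x) {
  if (is.list(x) && !is.null(x$recordings)) return(x)
  # manifest path on disk
  man <- read_manifest(x)
  recs <- list()
  for (i in seq_len(nrow(man$trials))) {
    tr <- man$trials[i, ]
    key <- paste(tr$participant, tr$session, tr$activity, sep = "|")
    meta <- list(participant = tr$participant, device = tr$device,
                 location = tr$location, session = tr$session,
                 activity = tr$activity, sample_rate = man$sample_rate)
    rec <- read_recording(tr$path, meta)
    if (tr$activity == "walk" && is.null(rec$walk_direction)) {
      rec$walk_direction <- spans_to_flags(man$direction_spans[[key]],
                                           nrow(rec$quat))
      rec <- validate_recording(rec)
    }
    recs[[paste(tr$participant, tr$session, tr$activity, tr$device,
                tr$location, sep = "|")]] <- rec
  }
  list(manifest = man, recordings = recs)
}

#' Process a cohort of recordings into cycles and a range table
#'
#' Runs the full conditioning and segmentation chain for every
#' (participant, session, activity, device) trial: each device's streams are
#' segmented by that device's own thigh-orientation boundaries, end cycles
#' are discarded, cycles are normalized to 101 points, and per-cycle ranges
#' are averaged per participant.
#'
#' @param cohort a cohort object from [generate_cohort()] (in-memory
#'   recordings) or the path to a `manifest.yaml` on disk.
#' @param config a [pipeline_config()].
#' @param devices,sessions optional subsets to process.
#' @return list with `range_table` (participant-level, see
#'   [aggregate_ranges()]), `cycles` (named list keyed
#'   `participant|session|activity|device|location|quantity|axis` of
#'   101 x n_cycles matrices), and `log` (per-trial detected/retained cycle
#'   counts).
#' @export
process_cohort <- function(cohort, config = pipeline_config(),
                           devices = NULL, sessions = NULL) {
  cohort <- load_cohort_recordings(cohort)
  keys <- names(cohort$recordings)
  info <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  colnames(info) <- c("participant", "session", "activity", "device", "location")
  info <- as.data.frame(info)
  info$session <- as.integer(info$session)
  if (!is.null(devices)) info <- info[info$device %in% devices, ]
  if (!is.null(sessions)) info <- info[info$session %in% sessions, ]

  trials <- unique(info[c("participant", "session", "activity", "device")])
  cycles <- list(); rows <- list(); logs <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    recs <- list()
    for (loc in LOCATIONS) {
      k <- paste(tr$participant, tr$session, tr$activity, tr$device, loc, sep = "|")
      if (!is.null(cohort$recordings[[k]])) recs[[loc]] <- cohort$recordings[[k]]
    }
    out <- process_device_trial(recs, config)
    logs[[i]] <- data.frame(tr, n_troughs = out$n_troughs,
                            n_detected = out$n_detected,
                            n_retained = out$n_retained)
    if (out$n_retained == 0) {
      warning(sprintf("no retained cycles for %s s%d %s %s; trial skipped",
                      tr$participant, tr$session, tr$activity, tr$device))
      next
    }
    for (nm in names(out$cycles)) {
      cycles[[paste(tr$participant, tr$session, tr$activity, tr$device, nm,
                    sep = "|")]] <- out$cycles[[nm]]
    }
    cr <- out$cycle_ranges
    cr$participant <- tr$participant; cr$device <- tr$device
    cr$session <- tr$session; cr$activity <- tr$activity
    rows[[i]] <- cr
  }
  cycle_ranges <- do.call(rbind, rows)
  list(range_table = aggregate_ranges(cycle_ranges),
       cycles = cycles, log = do.call(rbind, logs))
}

case_grid <- function(activities, quantities = c("acc", "ori")) {
  grid <- expand.grid(activity = activities, location = LOCATIONS,
                      axis = AXES, quantity = quantities,
                      stringsAsFactors = FALSE)
  norm <- expand.grid(activity = activities, location = LOCATIONS,
                      axis = "norm", quantity = "acc_norm",
                      stringsAsFactors = FALSE)
  rbind(grid, norm)
}

#' Concurrent-validity report for a processed cohort
#'
#' For every case (activity x location x axis, per quantity) of the first
#' session: per-participant Linear Fit Method between the test and criterion
#' device's normalized cycles (paired by cycle index), summarized across
#' participants, and Bland-Altman statistics (criterion - test) on the
#' participant range values.
#'
#' @param processed output of [process_cohort()] covering both devices in
#'   session 1.
#' @param config a [pipeline_config()].
#' @param session session to compare (default 1).
#' @return list with `cases` (one row per case: LFM summary, Bland-Altman
#'   fields, validity class) and `summary` ([classification_summary()] per
#'   quantity). Cases missing a device are skipped with a warning.
#' @export
run_validity <- function(processed, config = pipeline_config(), session = 1) {
  rt <- processed$range_table
  rt <- rt[rt$session == session, ]
  if (!nrow(rt)) stop_named("imuagree_precondition", "no session-%d data", session)
  grid <- case_grid(sort(unique(rt$activity)))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sub <- rt[rt$activity == g$activity & rt$location == g$location &
                rt$quantity == g$quantity & rt$axis == g$axis, ]
    parts <- intersect(sub$participant[sub$device == "test"],
                       sub$participant[sub$device == "criterion"])
    if (!length(parts)) {
      warning(sprintf("case %s/%s/%s/%s lacks a device pair; skipped",
                      g$activity, g$location, g$quantity, g$axis))
      next
    }
    fits <- lapply(parts, function(p) {
      kt <- paste(p, session, g$activity, "test", g$location, g$quantity,
                  g$axis, sep = "|")
      kc <- paste(p, session, g$activity, "criterion", g$location, g$quantity,
                  g$axis, sep = "|")
      lfm_participant(processed$cycles[[kt]], processed$cycles[[kc]],
                      mode = config$lfm_mode)
    })
    sm <- lfm_summary(fits)
    tv <- sub$range_value[sub$device == "test"][match(parts, sub$participant[sub$device == "test"])]
    cv <- sub$range_value[sub$device == "criterion"][match(parts, sub$participant[sub$device == "criterion"])]
    ba <- if (length(parts) >= 2) bland_altman(tv, cv) else NULL
    out[[i]] <- cbind(g, sm, data.frame(
      mean_diff = if (is.null(ba)) NA_real_ else ba$mean_diff,
      sd_diff = if (is.null(ba)) NA_real_ else ba$sd_diff,
      loa_lower = if (is.null(ba)) NA_real_ else ba$loa_lower,
      loa_upper = if (is.null(ba)) NA_real_ else ba$loa_upper,
      ci95_lower = if (is.null(ba)) NA_real_ else ba$ci95_mean_diff[1],
      ci95_upper = if (is.null(ba)) NA_real_ else ba$ci95_mean_diff[2]))
  }
  cases <- do.call(rbind, out)
  if (is.null(cases)) {
    warning("no device-paired cases; empty validity report")
    return(list(cases = grid[0, ], summary = list()))
  }
  rownames(cases) <- NULL
  summary <- lapply(split(cases, cases$quantity), function(d) {
    classification_summary(d$class,
                           levels = c("excellent", "fair_to_good", "poor"))
  })
  list(cases = cases, summary = summary)
}

#' Test-retest reliability report for a processed cohort
#'
#' For every case of the test device: ICC(C,1) with its 95% CI between the
#' two sessions of `session_pair`, the SEM from the across-participant SD of
#' each participant's session-mean range value, and the reliability class.
#'
#' @param processed output of [process_cohort()], or a range table data
#'   frame, covering the test device in both sessions.
#' @param session_pair integer pair, e.g. `c(1, 2)` (researcher-attached
#'   retest) or `c(1, 3)` (participant-attached retest).
#' @param config a [pipeline_config()].
#' @param device device to evaluate (default `"test"`).
#' @return list with `cases` (one row per case: icc, ci, sem, sd_used,
#'   class, n) and `summary` (classification proportions per quantity).
#'   Participants missing either session are excluded.
#' @export
run_reliability <- function(processed, session_pair = c(1, 2),
                            config = pipeline_config(), device = "test") {
  rt <- if (is.data.frame(processed)) processed else processed$range_table
  rt <- rt[rt$device == device & rt$session %in% session_pair, ]
  if (!nrow(rt)) stop_named("imuagree_precondition", "no data for device/sessions")
  grid <- case_grid(sort(unique(rt$activity)))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sub <- rt[rt$activity == g$activity & rt$location == g$location &
                rt$quantity == g$quantity & rt$axis == g$axis, ]
    s1 <- sub[sub$session == session_pair[1], ]
    s2 <- sub[sub$session == session_pair[2], ]
    parts <- intersect(s1$participant, s2$participant)
    if (length(parts) < 2) {
      warning(sprintf("case %s/%s/%s/%s has < 2 complete participants; skipped",
                      g$activity, g$location, g$quantity, g$axis))
      next
    }
    m <- cbind(s1$range_value[match(parts, s1$participant)],
               s2$range_value[match(parts, s2$participant)])
    res <- icc_consistency(m, form = config$icc_form)
    sd_used <- stats::sd(rowMeans(m))
    out[[i]] <- cbind(g, data.frame(
      icc = res$icc, ci95_lower = res$ci95[1], ci95_upper = res$ci95[2],
      sem = sem_from_icc(sd_used, min(res$icc, 1)), sd_used = sd_used,
      class = res$class, n_participants = length(parts)))
  }
  cases <- do.call(rbind, out)
  if (is.null(cases)) {
    warning("no case with two complete sessions; empty reliability report")
    return(list(cases = grid[0, ], summary = list(),
                session_pair = session_pair))
  }
  rownames(cases) <- NULL
  summary <- lapply(split(cases, cases$quantity), function(d) {
    classification_summary(d$class,
                           levels = c("excellent", "fair_to_high", "poor"))
  })
  list(cases = cases, summary = summary, session_pair = session_pair)
}
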