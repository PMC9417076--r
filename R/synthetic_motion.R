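# Synthetic dual-sensor motion: ground-truth segment kinematics with known
# amplitude, distortion and variance-component parameters, so that every
# downstream estimator (LFM, Bland-Altman, ICC, SEM) can be checked by
# parameter recovery. Waveforms are sums of 1-3 harmonics of the cycle
# frequency per location/axis, with activity-specific amplitudes; jumps add
# an exponentially decaying high-frequency landing transient, walking
# includes a direction reversal at the trial midpoint. The thigh-orientation
# x waveform is dominated by its first harmonic, guaranteeing exactly one
# prominent trough per cycle flanked by maxima.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# harmonic waveform over phase in [0, 1): off + A * sum_h a_h cos(2 pi h phi + p_h)
harm <- function(phi, off, A, a = 1, p = 0, h = seq_along(a)) {
  y <- rep(off, length(phi))
  for (i in seq_along(a)) y <- y + A * a[i] * cos(2 * pi * h[i] * phi + p[i])
  y
}

# per-activity waveform parameters: amplitudes in degrees (ori) / m/s^2 (acc)
activity_params <- function(activity) {
  base <- switch(activity,
    squat = list(period = 3.0, thigh_x = 40,
      ori = list(sacrum = c(z = 5, x = 15, y = 6), thigh = c(z = 8, x = 40, y = 6),
                 shank = c(z = 5, x = 25, y = 6)),
      acc = list(sacrum = c(z = 2.0, x = 0.8, y = 0.6),
                 thigh = c(z = 1.5, x = 1.0, y = 0.7),
                 shank = c(z = 1.0, x = 0.8, y = 0.9)),
      burst = 0),
    jump = list(period = 1.5, thigh_x = 30,
      ori = list(sacrum = c(z = 6, x = 12, y = 7), thigh = c(z = 8, x = 30, y = 8),
                 shank = c(z = 6, x = 22, y = 7)),
      acc = list(sacrum = c(z = 8, x = 2.5, y = 2.0),
                 thigh = c(z = 7, x = 3.0, y = 2.5),
                 shank = c(z = 6, x = 3.5, y = 3.0)),
      burst = 5),
    walk = list(period = 1.1, thigh_x = 20,
      ori = list(sacrum = c(z = 5, x = 6, y = 5), thigh = c(z = 7, x = 20, y = 6),
                 shank = c(z = 8, x = 35, y = 7)),
      acc = list(sacrum = c(z = 2.5, x = 2.0, y = 1.5),
                 thigh = c(z = 3.0, x = 2.5, y = 2.0),
                 shank = c(z = 4.0, x = 3.5, y = 2.5)),
      burst = 0),
    stair_ascent = list(period = 1.4, thigh_x = 35,
      ori = list(sacrum = c(z = 6, x = 10, y = 6), thigh = c(z = 8, x = 35, y = 7),
                 shank = c(z = 7, x = 30, y = 7)),
      acc = list(sacrum = c(z = 2.5, x = 1.8, y = 1.4),
                 thigh = c(z = 3.0, x = 2.2, y = 1.8),
                 shank = c(z = 3.5, x = 2.8, y = 2.2)),
      burst = 0),
    stair_descent = list(period = 1.4, thigh_x = 35,
      ori = list(sacrum = c(z = 6, x = 9, y = 6), thigh = c(z = 8, x = 35, y = 7),
                 shank = c(z = 7, x = 28, y = 7)),
      acc = list(sacrum = c(z = 3.0, x = 2.0, y = 1.6),
                 thigh = c(z = 3.5, x = 2.5, y = 2.0),
                 shank = c(z = 4.2, x = 3.2, y = 2.6)),
      burst = 0),
    stop_named("imuagree_precondition", "unknown activity: %s", activity)
  )
  base
}

DEFAULT_N_CYCLES <- c(squat = 8, jump = 8, walk = 20,
                      stair_ascent = 12, stair_descent = 12)

#' Generate ground-truth motion for one activity
#'
#' Produces continuous per-location orientation (intrinsic z-x-y Euler
#' angles, degrees) and free-acceleration (m/s^2, axis order z, x, y) signals
#' at 60 Hz, composed of activity-specific harmonics of the cycle frequency.
#' A small seeded per-cycle amplitude jitter (2% SD) makes repetitions
#' realistically non-identical without disturbing the extremum structure.
#'
#' @param activity one of `squat`, `jump`, `walk`, `stair_ascent`,
#'   `stair_descent`.
#' @param n_cycles number of movement cycles (>= 3 so at least one survives
#'   the end-discard); defaults per activity (8 squat/jump repetitions,
#'   20 walking strides, 12 stair cycles).
#' @param cycle_period cycle duration in seconds; activity default if `NULL`.
#' @param amplitude_scale global multiplier on all waveform amplitudes; must
#'   be nonzero (a zero amplitude yields constant signals with no detectable
#'   cycles and is rejected as degenerate).
#' @param sample_rate Hz (default 60).
#' @param seed integer seed; identical seeds give identical signals.
#' @return object of class `motion_truth`: lists `euler` and `acc` (one
#'   n x 3 matrix per location, columns z, x, y), `direction` flags for
#'   walking (reversal at the midpoint cycle boundary), and the generation
#'   parameters.
#' @export
generate_motion_truth <- function(activity, n_cycles = NULL, cycle_period = NULL,
                                  amplitude_scale = 1, sample_rate = 60,
                                  seed = 1) {
  activity <- match.arg(activity, ACTIVITIES)
  p <- activity_params(activity)
  n_cycles <- n_cycles %||% unname(DEFAULT_N_CYCLES[activity])
  if (n_cycles < 3) {
    stop_named("imuagree_precondition", "n_cycles must be >= 3, got %d", n_cycles)
  }
  if (amplitude_scale == 0) {
    stop_named("imuagree_degenerate",
               "amplitude_scale 0 gives constant signals with no detectable cycles")
  }
  cycle_period <- cycle_period %||% p$period
  stopifnot(cycle_period > 0)

  # a 0.15-cycle lead-in/lead-out emulates quiet standing around the trial
  # and keeps every cycle's flanking maxima interior to the signal
  pad <- 0.15
  n <- round((n_cycles + 2 * pad) * cycle_period * sample_rate) + 1L
  t <- (seq_len(n) - 1) / sample_rate - pad * cycle_period
  phi <- (t / cycle_period) %% 1
  cyc <- pmax(0, pmin(floor(t / cycle_period), n_cycles - 1))

  jitter <- with_seed(seed, 1 + 0.02 * stats::rnorm(n_cycles))
  jit <- jitter[cyc + 1]

  # axis-specific harmonic mixes; first harmonic dominates everywhere and the
  # thigh x angle keeps a single prominent trough per cycle
  mix <- list(z = list(a = c(1, 0.15), p = c(0.4, 1.1)),
              x = list(a = c(1, 0.15), p = c(0, 0.8)),
              y = list(a = c(1, 0.20, 0.05), p = c(1.2, 0.3, 2.0)))
  wave <- function(A, axis, center = 0) {
    m <- mix[[axis]]
    center + amplitude_scale * jit * (harm(phi, 0, A, m$a, m$p))
  }

  euler <- list(); acc <- list()
  for (loc in LOCATIONS) {
    e <- cbind(z = wave(p$ori[[loc]]["z"], "z"),
               x = wave(p$ori[[loc]]["x"], "x",
                        center = if (loc == "thigh") -10 else 0),
               y = wave(p$ori[[loc]]["y"], "y"))
    a <- cbind(z = wave(p$acc[[loc]]["z"], "z"),
               x = wave(p$acc[[loc]]["x"], "x"),
               y = wave(p$acc[[loc]]["y"], "y"))
    if (p$burst > 0) {
      tl <- (phi - 0.6) * cycle_period
      land <- ifelse(tl >= 0, exp(-tl / 0.05) * sin(2 * pi * 15 * tl), 0)
      bscale <- c(sacrum = 0.4, thigh = 0.8, shank = 1.0)[[loc]]
      a <- a + amplitude_scale * p$burst * bscale * jit * land
    }
    euler[[loc]] <- e; acc[[loc]] <- a
  }

  direction <- NULL
  if (activity == "walk") {
    direction <- ifelse(cyc < n_cycles / 2, 1, -1)
    for (loc in LOCATIONS) {
      acc[[loc]][, c("x", "y")] <- acc[[loc]][, c("x", "y")] * direction
    }
  }

  structure(list(activity = activity, sample_rate = sample_rate,
                 n_cycles = n_cycles, cycle_period = cycle_period,
                 amplitude_scale = amplitude_scale, n = n, time = t,
                 euler = euler, acc = acc, direction = direction, seed = seed),
            class = "motion_truth")
}

#' Construct a sensor distortion
#'
#' Describes how one device's view differs from the ground truth: a linear
#' gain/offset and additive Gaussian noise per channel (acceleration in
#' m/s^2, orientation in degrees), a small fixed mounting-misalignment
#' rotation, and an integer time lag.
#'
#' @param gain,offset,noise_sd acceleration channel: view =
#'   gain * (rotated, lagged truth) + offset + N(0, noise_sd^2); `noise_sd`
#'   may be length 3 for per-axis (z, x, y) noise.
#' @param ori_gain,ori_offset,ori_noise_sd same for the Euler orientation
#'   channel (applied in degrees before conversion back to quaternions).
#' @param misalign_zxy fixed sensor-frame rotation as intrinsic z-x-y angles
#'   in degrees (each |angle| <= 30).
#' @param lag time lag in samples (>= 0).
#' @return object of class `sensor_distortion`.
#' @export
sensor_distortion <- function(gain = 1, offset = 0, noise_sd = 0,
                              ori_gain = 1, ori_offset = 0, ori_noise_sd = 0,
                              misalign_zxy = c(0, 0, 0), lag = 0L) {
  stopifnot(gain > 0, ori_gain > 0, all(noise_sd >= 0), all(ori_noise_sd >= 0),
            length(noise_sd) %in% c(1L, 3L), length(ori_noise_sd) %in% c(1L, 3L),
            length(misalign_zxy) == 3, all(abs(misalign_zxy) <= 30), lag >= 0)
  structure(list(gain = gain, offset = offset, noise_sd = noise_sd,
                 ori_gain = ori_gain, ori_offset = ori_offset,
                 ori_noise_sd = ori_noise_sd, misalign_zxy = misalign_zxy,
                 lag = as.integer(lag)),
            class = "sensor_distortion")
}

lag_rows <- function(m, lag) {
  if (lag == 0L) return(m)
  n <- nrow(m)
  rbind(m[rep(1L, lag), , drop = FALSE], m[1:(n - lag), , drop = FALSE])
}

#' Render one sensor's view of a motion truth
#'
#' Applies a [sensor_distortion()] to the ground-truth streams of one body
#' location and packages the result as a [sensor_recording()]: acceleration
#' vectors are rotated by the misalignment, lagged, scaled, offset and
#' perturbed with Gaussian noise; Euler orientations are lagged, scaled,
#' offset, perturbed, converted to quaternions and composed with the
#' misalignment rotation.
#'
#' @param truth a `motion_truth` from [generate_motion_truth()].
#' @param location `"sacrum"`, `"thigh"` or `"shank"`.
#' @param dist a [sensor_distortion()]; identity by default.
#' @param meta list with `participant`, `device`, `session` for the recording.
#' @param seed integer seed for the noise draws.
#' @return a [sensor_recording()]; with the identity distortion its Euler
#'   angles and accelerations equal the truth to within 1e-9.
#' @export
render_sensor_view <- function(truth, location, dist = sensor_distortion(),
                               meta = list(participant = "P01", device = "test",
                                           session = 1L),
                               seed = 1) {
  location <- match.arg(location, LOCATIONS)
  n <- truth$n
  if (dist$lag >= n) {
    stop_named("imuagree_precondition", "lag (%d) >= signal length (%d)",
               dist$lag, n)
  }
  per_axis <- function(sd) {  # sd per (z, x, y) column
    sd <- rep(sd, length.out = 3)
    vapply(sd, function(s) stats::rnorm(n, 0, s), numeric(n))
  }
  noise <- with_seed(seed, list(acc = per_axis(dist$noise_sd),
                                ori = per_axis(dist$ori_noise_sd)))

  Rm <- quat_to_rotmat(misalignment_quat(dist$misalign_zxy))
  acc <- lag_rows(truth$acc[[location]], dist$lag)
  # rotation acts on (x, y, z) vectors; storage order is (z, x, y)
  axyz <- acc[, c("x", "y", "z")] %*% t(Rm)
  acc_v <- cbind(z = axyz[, 3], x = axyz[, 1], y = axyz[, 2])
  acc_v <- dist$gain * acc_v + dist$offset + noise$acc

  eul <- lag_rows(truth$euler[[location]], dist$lag)
  eul_v <- dist$ori_gain * eul + dist$ori_offset + noise$ori
  quat <- euler_zxy_to_quat(eul_v)
  if (any(dist$misalign_zxy != 0)) {
    quat <- quat_multiply(quat, misalignment_quat(dist$misalign_zxy))
  }
  quat <- quat_normalize(quat)

  sensor_recording(
    participant = meta$participant %||% "P01", device = meta$device %||% "test",
    location = location, session = meta$session %||% 1L,
    activity = truth$activity, quat = quat, free_acc = acc_v,
    sample_rate = truth$sample_rate,
    walk_direction = if (truth$activity == "walk") truth$direction else NULL
  )
}

#' Specify a synthetic cohort
#'
#' Variance components act on an amplitude multiplier
#' `1 + (b_i + w_is) / amp_ref` with participant effect
#' `b_i ~ N(0, var_between)` and session effect `w_is ~ N(0, var_within)`,
#' so every range outcome is a linear function of `b_i + w_is` and the true
#' intraclass correlation of range values across sessions is
#' `var_between / (var_between + var_within)`.
#'
#' @param n_participants number of participants (>= 2).
#' @param var_between,var_within between-participant and within-participant
#'   (between-session) variance components (>= 0).
#' @param placement_sd SD (degrees) of the per-session, per-device sensor
#'   placement rotation for researcher-attached sessions (1 and 2).
#' @param placement_sd_self same for the participant-attached session 3;
#'   defaults to `2.5 * placement_sd`.
#' @param amp_ref scaling that converts outcome effects to relative amplitude
#'   (default 10).
#' @param seed master integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants, var_between = 1, var_within = 0.25,
                        placement_sd = 0, placement_sd_self = NULL,
                        amp_ref = 10, seed = 1) {
  stopifnot(n_participants >= 2, var_between >= 0, var_within >= 0,
            placement_sd >= 0, amp_ref > 0)
  structure(list(n_participants = as.integer(n_participants),
                 var_between = var_between, var_within = var_within,
                 placement_sd = placement_sd,
                 placement_sd_self = placement_sd_self %||% (2.5 * placement_sd),
                 amp_ref = amp_ref, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' True intraclass correlation implied by a cohort specification
#'
#' @param spec a [cohort_spec()].
#' @return `var_between / (var_between + var_within)`.
#' @export
cohort_icc_true <- function(spec) {
  spec$var_between / (spec$var_between + spec$var_within)
}

#' Draw outcome values directly from a cohort's variance-component model
#'
#' Samples the subjects x sessions matrix `mu + b_i + w_is` that underlies
#' the cohort generator's amplitude multipliers, without rendering signals.
#' This is the ground-truth model against which ICC estimation is checked at
#' scales (hundreds of subjects, hundreds of replicates) where rendering and
#' processing full recordings would be pointless.
#'
#' @param spec a [cohort_spec()].
#' @param k_sessions number of sessions (columns).
#' @param mu grand mean (default 10).
#' @param seed optional seed override (defaults to `spec$seed`).
#' @return `n_participants` x `k_sessions` numeric matrix.
#' @export
sample_cohort_outcomes <- function(spec, k_sessions = 2, mu = 10, seed = NULL) {
  n <- spec$n_participants
  with_seed(seed %||% spec$seed, {
    b <- stats::rnorm(n, 0, sqrt(spec$var_between))
    w <- matrix(stats::rnorm(n * k_sessions, 0, sqrt(spec$var_within)),
                nrow = n)
    mu + b + w
  })
}

#' Generate a synthetic multi-session dual-device cohort
#'
#' For each participant and session, draws the amplitude multiplier from the
#' cohort's variance components, generates the motion truth, and renders one
#' recording per device and location (both devices view the same session's
#' truth, as in simultaneous data collection). Session-specific placement
#' error is added as an extra random mounting rotation per device and
#' location. Deterministic given `spec$seed`; per-participant seeds are
#' derived as seed + participant index.
#'
#' @param spec a [cohort_spec()].
#' @param activities character vector of activities to simulate.
#' @param distortions named list with elements `test` and `criterion`, each a
#'   [sensor_distortion()]; identity by default.
#' @param n_sessions 1-3 sessions.
#' @param devices devices to render (default both).
#' @param dir if non-`NULL`, recordings are written as CSVs plus a
#'   `manifest.yaml` under this directory (pre-existing target files are an
#'   error).
#' @return invisible list with `spec`, `manifest` (trials data frame +
#'   direction spans), `recordings` (named list keyed
#'   `participant|session|activity|device|location`), and `multipliers`
#'   (participant x session amplitude multipliers).
#' @export
generate_cohort <- function(spec, activities = "squat",
                            distortions = list(test = sensor_distortion(),
                                               criterion = sensor_distortion()),
                            n_sessions = 3, devices = DEVICES, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), n_sessions %in% 1:3)
  activities <- match.arg(activities, ACTIVITIES, several.ok = TRUE)
  n <- spec$n_participants
  ids <- sprintf("P%02d", seq_len(n))

  eff <- with_seed(spec$seed, {
    b <- stats::rnorm(n, 0, sqrt(spec$var_between))
    w <- matrix(stats::rnorm(n * n_sessions, 0, sqrt(spec$var_within)), nrow = n)
    mult <- 1 + (b + w) / spec$amp_ref
    # placement rotation per (participant, session, device, location):
    # sensors are attached once per session, shared by all activities
    place <- array(stats::rnorm(n * n_sessions * length(devices) * 3 * 3),
                   dim = c(n, n_sessions, length(devices), length(LOCATIONS), 3))
    list(mult = mult, place = place)
  })
  if (any(eff$mult < 0.05)) {
    warning("amplitude multipliers truncated at 0.05; variance components large relative to amp_ref")
    eff$mult[eff$mult < 0.05] <- 0.05
  }

  recordings <- list()
  trials <- list()
  spans <- list()
  for (i in seq_len(n)) {
    for (s in seq_len(n_sessions)) {
      psd <- if (s == 3) spec$placement_sd_self else spec$placement_sd
      for (act in activities) {
        truth <- generate_motion_truth(act, amplitude_scale = eff$mult[i, s],
                                       seed = spec$seed + i)
        if (act == "walk") {
          key <- paste(ids[i], s, act, sep = "|")
          d <- truth$direction
          edges <- c(1, which(diff(d) != 0) + 1, length(d) + 1)
          spans[[key]] <- data.frame(start = edges[-length(edges)],
                                     end = edges[-1] - 1,
                                     flag = d[edges[-length(edges)]])
        }
        for (di in seq_along(devices)) {
          dev <- devices[di]
          base_dist <- distortions[[dev]] %||% sensor_distortion()
          for (loc in LOCATIONS) {
            dist <- base_dist
            if (psd > 0) {
              dist$misalign_zxy <- dist$misalign_zxy +
                psd * eff$place[i, s, di, match(loc, LOCATIONS), ]
            }
            rec <- render_sensor_view(
              truth, loc, dist,
              meta = list(participant = ids[i], device = dev, session = s),
              seed = spec$seed + 7919L * i + 97L * s + 13L * di +
                match(loc, LOCATIONS) + 101L * match(act, ACTIVITIES))
            key <- paste(ids[i], s, act, dev, loc, sep = "|")
            recordings[[key]] <- rec
            trials[[key]] <- data.frame(
              participant = ids[i], session = s, activity = act,
              device = dev, location = loc,
              path = sprintf("%s_s%d_%s_%s_%s.csv", ids[i], s, act, dev, loc))
          }
        }
      }
    }
  }
  manifest <- list(sample_rate = 60, trials = do.call(rbind, trials),
                   direction_spans = spans)
  rownames(manifest$trials) <- NULL

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, manifest$trials$path)
    if (any(file.exists(paths))) {
      stop_named("imuagree_io", "conflicting output path(s): %s",
                 paths[file.exists(paths)][1])
    }
    for (k in seq_len(nrow(manifest$trials))) {
      key <- do.call(paste, c(manifest$trials[k, c("participant", "session",
                                                   "activity", "device",
                                                   "location")], sep = "|"))
      write_recording(recordings[[key]], paths[k])
    }
    write_manifest(manifest, file.path(dir, "manifest.yaml"))
  }

  invisible(list(spec = spec, activities = activities, manifest = manifest,
                 recordings = recordings, multipliers = eff$mult,
                 icc_true = cohort_icc_true(spec), dir = dir))
}
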