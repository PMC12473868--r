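#' Body locations analysed by the package
#'
#' The seven accelerometer placements supported throughout the package:
#' left/right wrist, chest, lower back, waist, thigh and ankle.
#'
#' @return Character vector of location tags.
#' @export
adl_locations <- function() {
  c("wrist_l", "wrist_r", "chest", "lower_back", "waist", "thigh", "ankle")
}

#' Standard gravity used throughout the package (m/s^2)
#' @return Numeric scalar, 9.80665.
#' @export
standard_gravity <- function() 9.80665

# Sensor dynamic range: +/- 8 g.
accel_range_ms2 <- function() 8 * standard_gravity()

# Per-location signal properties. `gain` attenuates the step impulse
# amplitude (strongest near the feet/pelvis, weakest and most
# artifact-contaminated at the wrists). Channel layout (vertical /
# anteroposterior / mediolateral index and vertical sign) varies by mounting
# so that downstream axis assignment is genuinely exercised.
location_properties <- function(location) {
  props <- list(
    wrist_l    = list(gain = 0.30, noise_sd = 0.12, artifact_mult = 3.0, artifact_amp = 2.0,
                      v = 1L, v_sign = -1, ap = 3L, ml = 2L),
    wrist_r    = list(gain = 0.28, noise_sd = 0.12, artifact_mult = 3.0, artifact_amp = 2.0,
                      v = 1L, v_sign = +1, ap = 2L, ml = 3L),
    chest      = list(gain = 0.50, noise_sd = 0.04, artifact_mult = 0.5, artifact_amp = 0.4,
                      v = 3L, v_sign = +1, ap = 1L, ml = 2L),
    lower_back = list(gain = 0.80, noise_sd = 0.04, artifact_mult = 0.5, artifact_amp = 0.4,
                      v = 3L, v_sign = -1, ap = 2L, ml = 1L),
    waist      = list(gain = 0.85, noise_sd = 0.04, artifact_mult = 0.5, artifact_amp = 0.4,
                      v = 2L, v_sign = +1, ap = 1L, ml = 3L),
    thigh      = list(gain = 0.72, noise_sd = 0.06, artifact_mult = 1.0, artifact_amp = 0.6,
                      v = 1L, v_sign = +1, ap = 3L, ml = 2L),
    ankle      = list(gain = 1.00, noise_sd = 0.08, artifact_mult = 1.0, artifact_amp = 0.6,
                      v = 2L, v_sign = -1, ap = 1L, ml = 3L)
  )
  props[[location]]
}

#' Define a synthetic gait profile for one subject
#'
#' Parameterizes the heterogeneous, bout-structured gait that the generator
#' emulates: slow and variable cadence, short irregular walking bouts
#' separated by rest or non-walking activity, a proportion of shuffling steps
#' (weight transfer without spatial displacement), lateral amplitude
#' asymmetry, and non-step arm/body movement artifacts.
#'
#' @param subject_id Unique subject identifier (string).
#' @param mean_cadence Mean within-bout step rate, steps/s. Must lie in (0, 3].
#' @param cadence_jitter_sd SD of the per-bout cadence draw, steps/s. Also
#'   scales small per-step timing jitter.
#' @param bout_length_range Length-2 numeric, min/max walking-bout duration (s).
#' @param rest_length_range Length-2 numeric, min/max rest duration between
#'   bouts (s). Rest periods may still contain non-step movement artifacts.
#' @param shuffle_fraction Probability that a step is a shuffling step
#'   (reduced vertical amplitude, no anteroposterior displacement signature).
#'   In \[0, 1\].
#' @param asymmetry_factor Amplitude ratio of affected to unaffected side
#'   steps (>= 0; 1 = symmetric gait).
#' @param adl_artifact_rate Rate of non-step movement bursts, events/min
#'   (scaled up at the wrists, down on the torso).
#' @param step_amplitude Peak vertical acceleration of an unattenuated
#'   walking step impulse, m/s^2 (before per-location attenuation).
#' @param noise_scale Multiplier on the per-location white-noise SD
#'   (0 = noiseless, for oracle checks).
#' @param seed Integer seed fixing every random draw for this subject.
#'
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id,
                            mean_cadence = 1.1,
                            cadence_jitter_sd = 0.1,
                            bout_length_range = c(4, 16),
                            rest_length_range = c(10, 40),
                            shuffle_fraction = 0.15,
                            asymmetry_factor = 0.7,
                            adl_artifact_rate = 2,
                            step_amplitude = 2.5,
                            noise_scale = 1,
                            seed = 1L) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L, nzchar(subject_id))
  if (!(mean_cadence > 0 && mean_cadence <= 3)) {
    abort_adlsteps("mean_cadence must lie in (0, 3] steps/s", "adlsteps_invalid_profile")
  }
  if (shuffle_fraction < 0 || shuffle_fraction > 1) {
    abort_adlsteps("shuffle_fraction must lie in [0, 1]", "adlsteps_invalid_profile")
  }
  if (asymmetry_factor < 0) {
    abort_adlsteps("asymmetry_factor must be >= 0", "adlsteps_invalid_profile")
  }
  stopifnot(length(bout_length_range) == 2L, bout_length_range[1] <= bout_length_range[2],
            bout_length_range[1] > 0,
            length(rest_length_range) == 2L, rest_length_range[1] <= rest_length_range[2],
            rest_length_range[1] >= 0,
            cadence_jitter_sd >= 0, adl_artifact_rate >= 0,
            step_amplitude > 0, noise_scale >= 0)
  structure(list(
    subject_id = subject_id, mean_cadence = mean_cadence,
    cadence_jitter_sd = cadence_jitter_sd,
    bout_length_range = as.numeric(bout_length_range),
    rest_length_range = as.numeric(rest_length_range),
    shuffle_fraction = shuffle_fraction, asymmetry_factor = asymmetry_factor,
    adl_artifact_rate = adl_artifact_rate, step_amplitude = step_amplitude,
    noise_scale = noise_scale, seed = as.integer(seed)
  ), class = "subject_profile")
}

#' Define a recording session
#'
#' @param duration Session length in seconds (> 0).
#' @param locations Character vector of sensor locations, a subset of
#'   [adl_locations()].
#' @param sample_rate Sampling rate in Hz (> 0, default 100).
#' @param gravity Gravitational acceleration, m/s^2.
#'
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(duration,
                         locations = adl_locations(),
                         sample_rate = 100,
                         gravity = standard_gravity()) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    abort_adlsteps("session duration must be a positive number of seconds",
                   "adlsteps_invalid_spec")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    abort_adlsteps("sample_rate must be positive", "adlsteps_invalid_spec")
  }
  bad <- setdiff(locations, adl_locations())
  if (length(bad)) {
    abort_adlsteps(paste0("unknown sensor location(s): ", paste(bad, collapse = ", ")),
                   "adlsteps_invalid_spec")
  }
  if (!length(locations)) abort_adlsteps("at least one location required", "adlsteps_invalid_spec")
  structure(list(duration = duration, locations = locations,
                 sample_rate = sample_rate, gravity = gravity),
            class = "session_spec")
}

# Construct an AccelRecording container (used by the generator and readers).
accel_recording <- function(subject_id, location, sample_rate, time, accel) {
  accel <- as.matrix(accel)
  colnames(accel) <- c("ax", "ay", "az")
  structure(list(subject_id = subject_id, location = location,
                 sample_rate = sample_rate, time = as.numeric(time),
                 accel = accel),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> subject %s, %s, %g Hz, %d samples (%.1f s)\n",
              x$subject_id, x$location, x$sample_rate, length(x$time),
              if (length(x$time)) diff(range(x$time)) + 1 / x$sample_rate else 0))
  invisible(x)
}

# Construct a StepAnnotationSet.
step_annotations <- function(events, excluded = NULL) {
  if (is.null(excluded)) {
    excluded <- data.frame(start_s = numeric(0), end_s = numeric(0))
  }
  events <- as.data.frame(events)
  stopifnot(all(c("time_s", "event_type") %in% names(events)))
  bad_type <- setdiff(unique(events$event_type), c("walking", "shuffling"))
  if (length(bad_type)) {
    abort_adlsteps(paste0("unknown event type(s): ", paste(bad_type, collapse = ", ")),
                   "adlsteps_invalid_annotation")
  }
  if (is.unsorted(events$time_s)) {
    abort_adlsteps("event times must be non-decreasing", "adlsteps_invalid_annotation")
  }
  excluded <- as.data.frame(excluded)
  if (nrow(excluded)) {
    stopifnot(all(c("start_s", "end_s") %in% names(excluded)))
    if (any(excluded$end_s <= excluded$start_s)) {
      abort_adlsteps("excluded intervals must satisfy start < end",
                     "adlsteps_invalid_annotation")
    }
    o <- order(excluded$start_s)
    excluded <- excluded[o, , drop = FALSE]
    if (nrow(excluded) > 1 &&
        any(excluded$start_s[-1] < excluded$end_s[-nrow(excluded)])) {
      abort_adlsteps("excluded intervals must not overlap", "adlsteps_invalid_annotation")
    }
  }
  structure(list(events = events, excluded = excluded), class = "step_annotations")
}

#' @export
print.step_annotations <- function(x, ...) {
  cat(sprintf("<step_annotations> %d events (%d walking, %d shuffling), %d excluded interval(s)\n",
              nrow(x$events), sum(x$events$event_type == "walking"),
              sum(x$events$event_type == "shuffling"), nrow(x$excluded)))
  invisible(x)
}

# Heel-strike-like transient: damped sinusoid normalized to unit peak.
# The 8 Hz carrier puts part of the impact energy above 5 Hz while the
# cadence-locked base component stays below 3 Hz.
step_impulse_shape <- function(sample_rate, dur = 0.4, carrier_hz = 8, tau = 0.07) {
  u <- seq(0, dur, by = 1 / sample_rate)
  s <- exp(-u / tau) * sin(2 * pi * carrier_hz * u)
  s / max(abs(s))
}

# Draw the bout/step schedule for one subject. Returns a data.frame with
# step time, type, side and per-step amplitude factor, plus bout intervals.
draw_step_schedule <- function(profile, duration) {
  steps <- list()
  bouts <- list()
  t <- runif(1, 0, max(profile$rest_length_range[2], 1e-9))
  t <- min(t, duration)
  side <- 0L
  while (t < duration - 0.05) {
    bout_len <- runif(1, profile$bout_length_range[1], profile$bout_length_range[2])
    bout_end <- min(t + bout_len, duration)
    cad <- rnorm(1, profile$mean_cadence, profile$cadence_jitter_sd)
    cad <- min(max(cad, 0.25), 3)
    bouts[[length(bouts) + 1L]] <- c(start = t, end = bout_end, cadence = cad)
    tt <- t + 0.5 / cad
    while (tt < bout_end && tt < duration - 0.05) {
      side <- 1L - side
      shuffle <- rbinom(1, 1, profile$shuffle_fraction) == 1L
      amp <- exp(rnorm(1, 0, 0.08)) *
        (if (shuffle) 0.4 else 1) *
        (if (side == 1L) profile$asymmetry_factor else 1)
      steps[[length(steps) + 1L]] <- data.frame(
        time_s = tt,
        event_type = if (shuffle) "shuffling" else "walking",
        amp = amp
      )
      tt <- tt + (1 / cad) * (1 + rnorm(1, 0, min(profile$cadence_jitter_sd, 0.1) * 0.3))
    }
    t <- bout_end + runif(1, profile$rest_length_range[1], profile$rest_length_range[2])
  }
  list(
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(time_s = numeric(0), event_type = character(0), amp = numeric(0)),
    bouts = bouts
  )
}

# Render the triaxial signal for one location given the shared schedule.
render_location_signal <- function(profile, spec, schedule, location) {
  fs <- spec$sample_rate
  n <- as.integer(round(spec$duration * fs))
  t <- (seq_len(n) - 1) / fs
  props <- location_properties(location)
  gain <- props$gain * profile$step_amplitude

  v <- numeric(n); ap <- numeric(n); ml <- numeric(n)

  # cadence-locked base oscillation during bouts, phase-aligned so maxima
  # fall at step times (first step is half a period into the bout)
  for (b in schedule$bouts) {
    idx <- which(t >= b["start"] & t < b["end"])
    if (!length(idx)) next
    ph <- 2 * pi * b["cadence"] * (t[idx] - b["start"] - 0.5 / b["cadence"])
    v[idx] <- v[idx] + 0.30 * gain * cos(ph)
    ap[idx] <- ap[idx] + 0.15 * gain * sin(ph)
    ml[idx] <- ml[idx] + 0.10 * gain * cos(ph / 2)
  }

  # per-step heel-strike transients
  shape <- step_impulse_shape(fs)
  m <- length(shape)
  st <- schedule$steps
  if (nrow(st)) {
    for (i in seq_len(nrow(st))) {
      i0 <- as.integer(round(st$time_s[i] * fs)) + 1L
      if (i0 > n) next
      i1 <- min(i0 + m - 1L, n)
      seg <- seq_len(i1 - i0 + 1L)
      a <- gain * st$amp[i]
      v[i0:i1] <- v[i0:i1] + a * shape[seg]
      if (st$event_type[i] == "walking") {
        # forward-displacement signature; absent for shuffling
        ap[i0:i1] <- ap[i0:i1] + 0.5 * a * shape[seg] * cos(2 * pi * 2 * (seg - 1) / fs)
      }
    }
  }

  # non-step ADL movement bursts (arm swings, reaching, etc.)
  rate <- profile$adl_artifact_rate * props$artifact_mult
  n_art <- if (rate > 0) rpois(1, rate / 60 * spec$duration) else 0L
  if (n_art > 0) {
    for (k in seq_len(n_art)) {
      dur <- runif(1, 1, 5)
      t0 <- runif(1, 0, max(spec$duration - dur, 0))
      f <- runif(1, 0.3, 2.0)
      amp <- runif(1, 0.5, 1.5) * props$artifact_amp
      idx <- which(t >= t0 & t < t0 + dur)
      if (!length(idx)) next
      u <- t[idx] - t0
      burst <- amp * sin(pi * u / dur) * sin(2 * pi * f * u)
      w <- rnorm(3); w <- w / sqrt(sum(w^2))
      v[idx] <- v[idx] + w[1] * burst
      ap[idx] <- ap[idx] + w[2] * burst
      ml[idx] <- ml[idx] + w[3] * burst
    }
  }

  nsd <- props$noise_sd * profile$noise_scale
  if (nsd > 0) {
    v <- v + rnorm(n, 0, nsd)
    ap <- ap + rnorm(n, 0, nsd)
    ml <- ml + rnorm(n, 0, nsd)
  }
  v <- v + spec$gravity

  accel <- matrix(0, n, 3)
  accel[, props$v] <- props$v_sign * v
  accel[, props$ap] <- ap
  accel[, props$ml] <- ml
  lim <- accel_range_ms2()
  accel[accel > lim] <- lim
  accel[accel < -lim] <- -lim
  accel_recording(profile$subject_id, location, fs, t, accel)
}

#' Simulate one annotated multi-sensor recording session
#'
#' Generates a triaxial recording for every requested sensor location, all on
#' an identical time base, together with the ground-truth step annotation
#' set. The signal model is: constant gravity on the location's vertical
#' axis; a cadence-locked base oscillation plus a damped-sinusoid transient
#' per step (amplitude attenuated per location, highest near ankle/waist,
#' lowest and most artifact-contaminated at the wrists); shuffling steps with
#' 40% vertical amplitude and no anteroposterior signature; smooth non-step
#' movement bursts; and white noise. All samples are clipped to the sensor
#' range of +/- 8 g. Annotation times mark the foot-reload moment and are
#' identical across locations.
#'
#' @param profile A [subject_profile()].
#' @param spec A [session_spec()].
#' @param excluded Optional data.frame (`start_s`, `end_s`) of intervals to
#'   mark as excluded in the annotation set (e.g., simulated video occlusion).
#'
#' @return A list with elements `recordings` (named list of
#'   `accel_recording`, one per location) and `annotations`
#'   (`step_annotations`).
#' @export
simulate_session <- function(profile, spec, excluded = NULL) {
  stopifnot(inherits(profile, "subject_profile"), inherits(spec, "session_spec"))
  schedule <- with_seed(profile$seed, draw_step_schedule(profile, spec$duration))
  recordings <- lapply(spec$locations, function(loc) {
    with_seed(derive_seed(profile$seed, paste0(profile$subject_id, "/", loc)),
              render_location_signal(profile, spec, schedule, loc))
  })
  names(recordings) <- spec$locations
  ann <- step_annotations(
    data.frame(time_s = schedule$steps$time_s,
               event_type = schedule$steps$event_type),
    excluded = excluded
  )
  list(recordings = recordings, annotations = ann)
}

#' Simulate an annotated cohort
#'
#' @param profiles List of [subject_profile()]s with unique subject IDs
#'   (at least 2: downstream leave-one-subject-out validation needs multiple
#'   subjects).
#' @param spec A [session_spec()] shared by all subjects.
#' @param master_seed Optional integer. When supplied, each profile's seed is
#'   replaced by a stream derived from `(master_seed, subject_id)`, making
#'   the cohort reproducible independent of generation order.
#'
#' @return An object of class `adl_cohort`: a list of per-subject lists with
#'   `profile`, `recordings`, and `annotations`.
#' @export
simulate_cohort <- function(profiles, spec, master_seed = NULL) {
  if (!length(profiles)) abort_adlsteps("empty profile list", "adlsteps_invalid_cohort")
  if (length(profiles) < 2L) {
    abort_adlsteps("a cohort needs at least 2 subjects", "adlsteps_invalid_cohort")
  }
  ids <- vapply(profiles, function(p) p$subject_id, character(1))
  if (anyDuplicated(ids)) {
    abort_adlsteps("duplicate subject IDs in cohort", "adlsteps_invalid_cohort")
  }
  out <- lapply(profiles, function(p) {
    if (!is.null(master_seed)) p$seed <- derive_seed(master_seed, p$subject_id)
    sess <- simulate_session(p, spec)
    list(profile = p, recordings = sess$recordings, annotations = sess$annotations)
  })
  names(out) <- ids
  structure(out, class = "adl_cohort")
}

#' Default cohort profiles emulating heterogeneous impaired gait
#'
#' Builds `n` subject profiles whose overall step rate targets a cohort mean
#' of `target_rate` steps/s (the fragmented activity level typical of
#' unscripted daily living in a neurological population), with substantial
#' between-subject spread. Cadence, bout structure, shuffling proportion and
#' asymmetry vary across subjects; rest durations are set so that each
#' subject's expected overall rate (cadence x active fraction) matches their
#' individual target.
#'
#' @param n Number of subjects (default 7).
#' @param master_seed Integer master seed; per-subject streams are derived
#'   from it.
#' @param target_rate Cohort-mean overall step rate, steps/s (default 0.37).
#'
#' @return List of [subject_profile()]s.
#' @export
default_cohort_profiles <- function(n = 7, master_seed = 1L, target_rate = 0.37) {
  if (n < 2) {
    abort_adlsteps("a cohort needs at least 2 subjects (LOSO holds one out)",
                   "adlsteps_invalid_cohort")
  }
  mult <- seq(0.6, 1.4, length.out = n)          # mean exactly 1
  rates <- target_rate * mult
  cadences <- 0.8 + 0.6 * (mult - 0.6) / 0.8     # 0.8 .. 1.4 steps/s
  shuffles <- seq(0.25, 0.05, length.out = n)
  asym <- seq(0.55, 0.95, length.out = n)
  bout_range <- c(4, 16)
  lapply(seq_len(n), function(i) {
    id <- sprintf("S%02d", i)
    duty <- rates[i] / cadences[i]
    rest_mean <- mean(bout_range) * (1 / duty - 1)
    subject_profile(
      subject_id = id,
      mean_cadence = cadences[i],
      cadence_jitter_sd = 0.1,
      bout_length_range = bout_range,
      rest_length_range = rest_mean * c(0.5, 1.5),
      shuffle_fraction = shuffles[i],
      asymmetry_factor = asym[i],
      adl_artifact_rate = 2,
      seed = derive_seed(master_seed, id)
    )
  })
}

#' Overall step rate realized by a cohort
#'
#' Total annotated step events divided by total recorded time, steps/s.
#'
#' @param cohort An `adl_cohort`.
#' @param duration Session duration in seconds (shared by all subjects).
#' @return Numeric scalar, steps/s.
#' @export
cohort_step_rate <- function(cohort, duration) {
  total <- sum(vapply(cohort, function(s) nrow(s$annotations$events), numeric(1)))
  total / (length(cohort) * duration)
}
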