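#' Threshold-crossing counter parameters
#'
#' @param threshold Detection threshold on the gravity-referenced vector
#'   magnitude, m/s^2 (default 0.3). A threshold this small is only
#'   meaningful after referencing to gravity: the raw magnitude is ~9.81
#'   m/s^2 at rest.
#' @param refractory Dead time after each detection, s (default 0.25,
#'   capping detections at 4 steps/s, above the ~3 Hz gait fundamental).
#' @param magnitude_mode `"gravity_subtracted"` (|a| - g) or `"bandpassed"`
#'   (narrow-band filtered magnitude).
#' @return An object of class `tca_params`.
#' @export
tca_params <- function(threshold = 0.3, refractory = 0.25,
                       magnitude_mode = c("gravity_subtracted", "bandpassed")) {
  stopifnot(threshold > 0, refractory >= 0)
  structure(list(threshold = threshold, refractory = refractory,
                 magnitude_mode = match.arg(magnitude_mode)),
            class = "tca_params")
}

#' Threshold-crossing step counter (TCA)
#'
#' Detects a step at every upward crossing of a fixed threshold by the
#' gravity-referenced acceleration vector magnitude; crossings within the
#' refractory period of the previous detection are ignored (greedy
#' earliest-first, which makes the count monotone non-increasing in the
#' threshold).
#'
#' @param rec An `accel_recording`.
#' @param params A [tca_params()].
#' @return List with `total` (count) and `event_times` (s).
#' @export
tca_count <- function(rec, params = tca_params()) {
  stopifnot(inherits(rec, "accel_recording"))
  mag <- sqrt(rowSums(rec$accel^2))
  s <- if (params$magnitude_mode == "gravity_subtracted") {
    mag - standard_gravity()
  } else {
    tmp <- rec
    tmp$accel <- cbind(mag, 0, 0)
    apply_filter(tmp, "narrow")$accel[, 1]
  }
  thr <- params$threshold
  up <- which(s[-1] >= thr & s[-length(s)] < thr) + 1L
  if (!length(up)) return(list(total = 0L, event_times = numeric(0)))
  times <- rec$time[up]
  kept <- times[1]
  last <- times[1]
  for (tt in times[-1]) {
    if (tt - last >= params$refractory) {
      kept <- c(kept, tt)
      last <- tt
    }
  }
  list(total = length(kept), event_times = kept)
}

#' Morlet wavelet counter parameters
#'
#' @param freq_range Scale search range expressed in Hz (default 0.5-3, the
#'   gait fundamental band).
#' @param n_scales Number of geometrically spaced scales (default 12).
#' @param peak_prominence_fraction Peak prominence gate as a fraction of the
#'   coefficient-series SD (default 0.5).
#' @param min_amplitude Absolute prominence floor in m/s^2-equivalent
#'   coefficient units (default 0.15); suppresses detections on the noise
#'   floor.
#' @param segment_length Scale-adaptation granularity, s (default 5;
#'   non-overlapping segments each select their own dominant scale, which is
#'   how the counter adapts to walking speed).
#' @return An object of class `cwt_params`.
#' @export
cwt_params <- function(freq_range = c(0.5, 3), n_scales = 12,
                       peak_prominence_fraction = 0.5, min_amplitude = 0.15,
                       segment_length = 5) {
  stopifnot(length(freq_range) == 2, freq_range[1] > 0,
            freq_range[2] > freq_range[1], n_scales >= 2,
            peak_prominence_fraction >= 0, min_amplitude >= 0, segment_length > 0)
  structure(list(freq_range = freq_range, n_scales = n_scales,
                 peak_prominence_fraction = peak_prominence_fraction,
                 min_amplitude = min_amplitude, segment_length = segment_length),
            class = "cwt_params")
}

# Analytic Morlet CWT (omega0 = 6) of a real signal, computed in the Fourier
# domain, one column per scale. Each scale's response is normalized so a
# unit-amplitude sinusoid at the scale's centre frequency yields |W| ~ 1,
# which keeps coefficient magnitudes in signal units.
morlet_cwt <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  xf <- stats::fft(x)
  omega_k <- 2 * pi * fs * c(0, seq_len(n - 1)) / n
  omega_k[omega_k > pi * fs] <- omega_k[omega_k > pi * fs] - 2 * pi * fs
  W <- matrix(0 + 0i, n, length(freqs))
  for (j in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[j])
    H <- ifelse(omega_k > 0, 2 * exp(-0.5 * (s * omega_k - omega0)^2), 0)
    W[, j] <- stats::fft(xf * H, inverse = TRUE) / n
  }
  W
}

#' Morlet continuous-wavelet step counter (CWT)
#'
#' Transforms the sign-corrected vertical channel with an analytic Morlet
#' wavelet over scales spanning the gait band, selects the dominant scale
#' within each non-overlapping segment (adapting to walking speed), and
#' counts prominent peaks of the coefficient series at the locally dominant
#' scale as steps.
#'
#' @param rec An `accel_recording`.
#' @param params A [cwt_params()].
#' @return List with `total`, `event_times` (s) and `segment_freqs` (the
#'   dominant frequency chosen per segment, Hz).
#' @export
cwt_count <- function(rec, params = cwt_params()) {
  stopifnot(inherits(rec, "accel_recording"))
  fs <- rec$sample_rate
  n <- nrow(rec$accel)
  s_max <- 6 / (2 * pi * params$freq_range[1])
  if (n / fs < 4 * s_max) {
    abort_adlsteps(sprintf("recording shorter than the largest wavelet support (%.1f s needed)",
                           4 * s_max), "adlsteps_cwt_error")
  }
  axes <- assign_axes(rec)
  v <- oriented_channels(rec, axes)$v
  v <- v - mean(v)
  freqs <- exp(seq(log(params$freq_range[1]), log(params$freq_range[2]),
                   length.out = params$n_scales))
  W <- morlet_cwt(v, fs, freqs)
  seg_len <- as.integer(round(params$segment_length * fs))
  n_seg <- ceiling(n / seg_len)
  series <- numeric(n)
  seg_freqs <- numeric(n_seg)
  for (g in seq_len(n_seg)) {
    i0 <- (g - 1L) * seg_len + 1L
    i1 <- min(g * seg_len, n)
    pw <- colMeans(Mod(W[i0:i1, , drop = FALSE])^2)
    j <- which.max(pw)
    seg_freqs[g] <- freqs[j]
    series[i0:i1] <- Re(W[i0:i1, j])
  }
  prom <- max(params$peak_prominence_fraction * sd(series), params$min_amplitude)
  pk <- find_peaks(series, min_prominence = prom,
                   min_separation = max(1, round(0.25 * fs)))
  list(total = length(pk), event_times = rec$time[pk], segment_freqs = seg_freqs)
}

# --- algorithm registry -----------------------------------------------------

counter_registry <- new.env(parent = emptyenv())

ensure_registry <- function() {
  if (length(ls(counter_registry))) return(invisible())
  assign("tca", list(
    fn = function(rec, ...) tca_count(rec, ...),
    available = TRUE,
    description = "threshold crossing on gravity-referenced magnitude"
  ), envir = counter_registry)
  assign("cwt", list(
    fn = function(rec, ...) cwt_count(rec, ...),
    available = TRUE,
    description = "Morlet wavelet peak counting, scale adapted to walking speed"
  ), envir = counter_registry)
  for (ext in c("skdh", "oxw")) {
    assign(ext, list(
      fn = NULL, available = FALSE,
      description = paste0("pre-trained external counter (", toupper(ext),
                           "); requires registration of an implementation")
    ), envir = counter_registry)
  }
  invisible()
}

#' Register a step-counting algorithm
#'
#' Adds (or replaces) an algorithm under the uniform
#' `function(recording) -> list(total, event_times)` contract, e.g. an
#' adapter around an externally trained counter.
#'
#' @param name Algorithm name.
#' @param fn Counting function.
#' @param description One-line description.
#' @return `name`, invisibly.
#' @export
register_step_counter <- function(name, fn, description = "") {
  ensure_registry()
  stopifnot(is.function(fn))
  assign(tolower(name), list(fn = fn, available = TRUE, description = description),
         envir = counter_registry)
  invisible(name)
}

#' List registered step-counting algorithms
#'
#' @return data.frame with `name`, `available`, `description`.
#' @export
step_counters <- function() {
  ensure_registry()
  nm <- sort(ls(counter_registry))
  data.frame(
    name = nm,
    available = vapply(nm, function(x) get(x, envir = counter_registry)$available, logical(1)),
    description = vapply(nm, function(x) get(x, envir = counter_registry)$description, character(1)),
    row.names = NULL
  )
}

#' Run a registered step counter on a recording
#'
#' External pre-trained counters (SKDH, OxW) are exposed through this
#' adapter: if no implementation has been registered, the call fails with an
#' explicit structured error — an unavailable counter is never silently
#' substituted.
#'
#' @param name Algorithm name (case-insensitive).
#' @param rec An `accel_recording`.
#' @param ... Passed to the counter.
#' @return List with at least `total` and `event_times`.
#' @export
count_steps <- function(name, rec, ...) {
  ensure_registry()
  key <- tolower(name)
  if (!exists(key, envir = counter_registry)) {
    abort_adlsteps(paste0("unknown step counter: ", name), "adlsteps_unknown_counter")
  }
  entry <- get(key, envir = counter_registry)
  if (!entry$available || is.null(entry$fn)) {
    abort_adlsteps(paste0("external counter not installed: ", name,
                          " (register an implementation with register_step_counter)"),
                   "adlsteps_external_unavailable")
  }
  res <- entry$fn(rec, ...)
  if (is.null(res$total) || res$total < 0) {
    abort_adlsteps(paste0("counter ", name, " returned an invalid count"),
                   "adlsteps_counter_contract")
  }
  res
}
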