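#' The three a priori filter bands
#'
#' Fifth-order Butterworth filters, always applied forward-backward
#' (zero phase): `wide` = low-pass at 15 Hz, `medium` = band-pass
#' 0.2-5 Hz, `narrow` = band-pass 0.5-3 Hz. Gait energy sits mostly below
#' 5 Hz with the fundamental below 3 Hz; the wide band retains impact
#' transients, the narrow band isolates the locomotor fundamental.
#'
#' @param name One of `"wide"`, `"medium"`, `"narrow"`.
#' @return An object of class `filter_band`.
#' @export
filter_band <- function(name = c("wide", "medium", "narrow")) {
  name <- match.arg(name)
  spec <- switch(name,
    wide   = list(kind = "lowpass",  low_cut = NA_real_, high_cut = 15),
    medium = list(kind = "bandpass", low_cut = 0.2,      high_cut = 5),
    narrow = list(kind = "bandpass", low_cut = 0.5,      high_cut = 3)
  )
  structure(c(list(name = name), spec, list(order = 5L, zero_phase = TRUE)),
            class = "filter_band")
}

#' Names of the three filter bands
#' @return Character vector `c("wide", "medium", "narrow")`.
#' @export
filter_band_names <- function() c("wide", "medium", "narrow")

#' Zero-phase Butterworth filtering of a recording
#'
#' Each channel is filtered independently with the band's 5th-order
#' Butterworth design, applied forward and backward so the output has zero
#' net phase. Output length equals input length.
#'
#' @param rec An `accel_recording`.
#' @param band A [filter_band()] or band name.
#' @return The filtered `accel_recording`.
#' @export
apply_filter <- function(rec, band) {
  stopifnot(inherits(rec, "accel_recording"))
  if (is.character(band)) band <- filter_band(band)
  fs <- rec$sample_rate
  if (fs <= 2 * band$high_cut) {
    abort_adlsteps("sample rate must exceed twice the band's upper cut-off",
                   "adlsteps_filter_error")
  }
  n <- nrow(rec$accel)
  # forward-backward IIR needs a few filter lengths of signal to settle
  min_len <- 3 * (2 * band$order + 1)
  if (n < min_len) {
    abort_adlsteps(sprintf("recording too short to filter (%d < %d samples)", n, min_len),
                   "adlsteps_filter_error")
  }
  bf <- if (band$kind == "lowpass") {
    signal::butter(band$order, band$high_cut / (fs / 2), type = "low")
  } else {
    signal::butter(band$order, c(band$low_cut, band$high_cut) / (fs / 2), type = "pass")
  }
  # odd-reflection padding keeps the forward-backward transients in the
  # discarded pad, not in the returned signal (matters for the slow 0.2-0.5 Hz
  # high-pass edges of the band-pass designs)
  low_edge <- if (band$kind == "lowpass") band$high_cut else band$low_cut
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / low_edge)))
  out <- rec
  for (j in 1:3) {
    x <- rec$accel[, j]
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    y <- as.numeric(signal::filtfilt(bf, xp))
    out$accel[, j] <- y[(pad + 1):(pad + n)]
  }
  out
}

#' Orientation-invariant axis assignment
#'
#' Identifies the vertical axis as the channel with the largest absolute
#' mean acceleration over the whole (unfiltered) recording — gravity marks
#' the vertical — with the sign chosen so the corrected vertical mean is
#' positive. The anteroposterior axis is the remaining channel with the
#' strongest absolute Pearson correlation to the corrected vertical channel.
#' Assign axes before band-pass filtering: the band-pass removes the gravity
#' cue this rule depends on.
#'
#' @param rec An `accel_recording`.
#' @return A list with `vertical_index`, `vertical_sign`,
#'   `anteroposterior_index`.
#' @export
assign_axes <- function(rec) {
  stopifnot(inherits(rec, "accel_recording"))
  if (!nrow(rec$accel)) abort_adlsteps("empty recording", "adlsteps_axis_error")
  mu <- colMeans(rec$accel)
  vi <- unname(which.max(abs(mu)))
  vsign <- if (mu[vi] >= 0) 1 else -1
  v <- rec$accel[, vi] * vsign
  rest <- setdiff(1:3, vi)
  vars <- apply(rec$accel[, rest, drop = FALSE], 2, stats::var)
  if (stats::var(v) == 0 || all(vars == 0)) {
    # degenerate constant channels: deterministic fallback
    api <- rest[1]
  } else {
    cors <- vapply(rest, function(j) {
      if (stats::var(rec$accel[, j]) == 0) return(0)
      abs(cor(rec$accel[, j], v))
    }, numeric(1))
    api <- rest[which.max(cors)]
  }
  list(vertical_index = vi, vertical_sign = vsign, anteroposterior_index = api)
}

#' Extract the sign-corrected vertical and anteroposterior channels
#'
#' @param rec An `accel_recording` (typically filtered).
#' @param axes Axis assignment from [assign_axes()] (computed on the
#'   unfiltered recording).
#' @return List with numeric vectors `v` and `ap`.
#' @export
oriented_channels <- function(rec, axes) {
  list(v = rec$accel[, axes$vertical_index] * axes$vertical_sign,
       ap = rec$accel[, axes$anteroposterior_index])
}

# TRUE for each window [start, end) that intersects any excluded interval.
window_excluded <- function(start, end, excluded) {
  if (is.null(excluded) || !nrow(excluded)) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    any(start[i] < excluded$end_s & end[i] > excluded$start_s)
  }, logical(1))
}

#' Segment a recording into labelled sliding windows
#'
#' Windows of `window_length` seconds with 50% overlap, starting at time 0
#' and lying fully inside the recording. The true step count of a window is
#' the number of annotated events in the half-open interval
#' \[start, end) — boundary events belong to the later window, so counts over
#' non-overlapping windows conserve the total. A window is invalid when it
#' intersects any excluded interval; invalid windows are dropped from
#' training and evaluation rather than partially labelled.
#'
#' @param rec An `accel_recording`.
#' @param annotations A `step_annotations` object.
#' @param window_length Window length in seconds (0.5, 2 or 5).
#' @param overlap Overlap fraction (default 0.5).
#' @return data.frame with columns `subject_id`, `start`, `end`,
#'   `true_step_count`, `valid`. Empty (zero rows) if the recording is
#'   shorter than one window.
#' @export
make_windows <- function(rec, annotations, window_length, overlap = 0.5) {
  stopifnot(inherits(rec, "accel_recording"), inherits(annotations, "step_annotations"))
  if (!window_length %in% c(0.5, 2, 5)) {
    abort_adlsteps("window_length must be one of 0.5, 2, 5 seconds", "adlsteps_window_error")
  }
  total <- nrow(rec$accel) / rec$sample_rate
  stride <- window_length * (1 - overlap)
  if (total < window_length - 1e-9) {
    return(data.frame(subject_id = character(0), start = numeric(0), end = numeric(0),
                      true_step_count = integer(0), valid = logical(0)))
  }
  starts <- seq(0, total - window_length + 1e-9, by = stride)
  ends <- starts + window_length
  ev <- annotations$events$time_s
  counts <- vapply(seq_along(starts), function(i) {
    sum(ev >= starts[i] & ev < ends[i])
  }, numeric(1))
  valid <- !window_excluded(starts, ends, annotations$excluded)
  data.frame(subject_id = rec$subject_id, start = starts, end = ends,
             true_step_count = as.integer(counts), valid = valid)
}
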