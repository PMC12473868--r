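#' Write a recording to delimited text
#'
#' Plain-text format with header `time_s,ax,ay,az`, acceleration in m/s^2 and
#' a monotone time column.
#'
#' @param rec An `accel_recording`.
#' @param path Output file path.
#' @param digits Significant digits for formatting (default 9).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 9) {
  stopifnot(inherits(rec, "accel_recording"))
  df <- data.frame(time_s = signif(rec$time, digits),
                   ax = signif(rec$accel[, 1], digits),
                   ay = signif(rec$accel[, 2], digits),
                   az = signif(rec$accel[, 3], digits))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Parses the `time_s,ax,ay,az` format, validating structure as it goes:
#' column count, numeric parsability, and a strictly increasing time column.
#' Sampling gaps larger than 50% of the nominal interval are flagged with a
#' warning (and recorded in the `gaps` attribute).
#'
#' @param path File path.
#' @param subject_id Subject identifier to attach.
#' @param location Sensor location tag (one of [adl_locations()]).
#' @param sample_rate Nominal sampling rate in Hz.
#' @return An `accel_recording`.
#' @export
read_recording <- function(path, subject_id, location, sample_rate = 100) {
  if (!file.exists(path)) abort_adlsteps(paste0("file not found: ", path), "adlsteps_io_error")
  if (!location %in% adl_locations()) {
    abort_adlsteps(paste0("unknown location: ", location), "adlsteps_io_error")
  }
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(trimws(header), c("time_s", "ax", "ay", "az"))) {
    abort_adlsteps(paste0("unexpected header in ", path,
                          " (want time_s,ax,ay,az)"), "adlsteps_parse_error")
  }
  lines <- readLines(path)[-1]
  fields <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    row <- which(nf != 4L)[1]
    abort_adlsteps(sprintf("row %d of %s has %d columns, expected 4", row, path, nf[row]),
                   "adlsteps_parse_error")
  }
  mat <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 4, byrow = TRUE))
  if (anyNA(mat)) {
    row <- which(rowSums(is.na(mat)) > 0)[1]
    abort_adlsteps(sprintf("unparseable number at row %d of %s", row, path),
                   "adlsteps_parse_error")
  }
  time <- mat[, 1]
  if (length(time) > 1) {
    dt <- diff(time)
    if (any(dt <= 0)) {
      row <- which(dt <= 0)[1] + 1L
      abort_adlsteps(sprintf("time not strictly increasing at row %d of %s", row, path),
                     "adlsteps_parse_error")
    }
  }
  rec <- accel_recording(subject_id, location, sample_rate, time, mat[, 2:4])
  if (length(time) > 1) {
    gap_rows <- which(diff(time) > 1.5 / sample_rate)
    if (length(gap_rows)) {
      warning(sprintf("%d sampling gap(s) detected in %s", length(gap_rows), path))
      attr(rec, "gaps") <- gap_rows
    }
  }
  rec
}

#' Write a step annotation set to delimited text
#'
#' Events go to `events_path` with header `time_s,event_type`
#' (`event_type` in walking/shuffling); excluded intervals go to a companion
#' file with header `start_s,end_s`.
#'
#' @param ann A `step_annotations` object.
#' @param events_path Path for the event file.
#' @param excluded_path Path for the excluded-intervals file.
#' @return `events_path`, invisibly.
#' @export
write_annotations <- function(ann, events_path, excluded_path) {
  stopifnot(inherits(ann, "step_annotations"))
  ev <- ann$events
  ev$time_s <- signif(ev$time_s, 9)
  write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
  write.csv(ann$excluded, excluded_path, row.names = FALSE, quote = FALSE)
  invisible(events_path)
}

#' Read a step annotation set
#'
#' Events with a type outside walking/shuffling are rejected, not dropped:
#' both types count as steps everywhere downstream.
#'
#' @param events_path Path to the event file (`time_s,event_type`).
#' @param excluded_path Optional path to the excluded-intervals file
#'   (`start_s,end_s`).
#' @param anchors Optional [sync_anchors()]. When given, event times and
#'   excluded intervals are assumed to be on the video clock and are mapped
#'   to the sensor clock once, at load.
#' @return A `step_annotations` object.
#' @export
read_annotations <- function(events_path, excluded_path = NULL, anchors = NULL) {
  ev <- read.csv(events_path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "event_type") %in% names(ev))) {
    abort_adlsteps("event file must have columns time_s,event_type", "adlsteps_parse_error")
  }
  ex <- NULL
  if (!is.null(excluded_path) && file.exists(excluded_path)) {
    ex <- read.csv(excluded_path, stringsAsFactors = FALSE)
    if (nrow(ex) && !all(c("start_s", "end_s") %in% names(ex))) {
      abort_adlsteps("excluded file must have columns start_s,end_s", "adlsteps_parse_error")
    }
  }
  if (!is.null(anchors)) {
    ev$time_s <- map_video_time(anchors, ev$time_s)
    if (!is.null(ex) && nrow(ex)) {
      ex$start_s <- map_video_time(anchors, ex$start_s)
      ex$end_s <- map_video_time(anchors, ex$end_s)
    }
  }
  step_annotations(ev, ex)
}

#' Video/sensor synchronization anchors
#'
#' Two paired time stamps (typically sensor taps visible on video at the
#' start and end of a recording) defining the affine map from the video clock
#' to the sensor clock.
#'
#' @param video_start,video_end Anchor times on the video clock (s).
#' @param sensor_start,sensor_end Matching times on the sensor clock (s).
#' @return An object of class `sync_anchors`.
#' @export
sync_anchors <- function(video_start, video_end, sensor_start, sensor_end) {
  if (!(video_end > video_start)) {
    abort_adlsteps("video_end must exceed video_start", "adlsteps_invalid_anchors")
  }
  if (!(sensor_end > sensor_start)) {
    abort_adlsteps("sensor_end must exceed sensor_start", "adlsteps_invalid_anchors")
  }
  structure(list(video_start = video_start, video_end = video_end,
                 sensor_start = sensor_start, sensor_end = sensor_end),
            class = "sync_anchors")
}

#' Map video-clock times to the sensor clock
#'
#' Exactly affine (linear interpolation between the two anchors): sends
#' `video_start` to `sensor_start` and `video_end` to `sensor_end`.
#'
#' @param anchors A [sync_anchors()].
#' @param t_video Numeric vector of video-clock times (s).
#' @return Sensor-clock times (s).
#' @export
map_video_time <- function(anchors, t_video) {
  stopifnot(inherits(anchors, "sync_anchors"))
  slope <- (anchors$sensor_end - anchors$sensor_start) /
    (anchors$video_end - anchors$video_start)
  anchors$sensor_start + slope * (t_video - anchors$video_start)
}
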