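#' Peak detection with prominence and separation gating
#'
#' Local maxima filtered by topographic prominence and a minimum peak
#' separation (higher peaks win ties). Used for the per-window peak-count
#' feature and by the wavelet baseline counter.
#'
#' @param x Numeric vector.
#' @param min_prominence Minimum prominence (same units as `x`).
#' @param min_separation Minimum distance between kept peaks, in samples.
#' @return Integer vector of peak indices, in increasing order.
#' @export
find_peaks <- function(x, min_prominence = 0, min_separation = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  # rising-then-falling sign changes; plateau peaks take the first index
  s <- sign(d)
  s_nz <- s
  for (i in seq_along(s_nz)) if (s_nz[i] == 0 && i > 1) s_nz[i] <- s_nz[i - 1]
  cand <- which(s_nz[-1] < 0 & s_nz[-length(s_nz)] > 0) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    # walk left to a strictly higher sample (or the edge), track the minimum
    j <- i; lmin <- h
    while (j > 1 && x[j] <= h) { j <- j - 1; lmin <- min(lmin, x[j]) }
    k <- i; rmin <- h
    while (k < n && x[k] <= h) { k <- k + 1; rmin <- min(rmin, x[k]) }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep) || min_separation <= 1) return(sort(keep))
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) || all(abs(sel - i) >= min_separation)) sel <- c(sel, i)
  }
  sort(sel)
}

#' Registry of per-window features
#'
#' Single source of truth for feature names, order and families. Time- and
#' frequency-domain features are computed per axis (vertical `v`,
#' anteroposterior `ap`); correlation features couple the two axes. Features
#' beyond the core set (range, RMS, IQR, spectral entropy, autocorrelation
#' peak) are flagged `extended`.
#'
#' @return data.frame with columns `name`, `family`, `extended`, in the
#'   fixed extraction order.
#' @export
feature_registry <- function() {
  per_axis <- function(axis) {
    data.frame(
      name = paste0(axis, "_", c("mean", "sd", "n_peaks", "range", "rms", "iqr",
                                 "spec_energy", "dom_freq", "dom_mag", "spec_entropy",
                                 "autocorr_peak")),
      family = c(rep("time", 6), rep("frequency", 4), "correlation"),
      extended = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                   FALSE, FALSE, FALSE, TRUE, TRUE)
    )
  }
  rbind(per_axis("v"), per_axis("ap"),
        data.frame(name = c("xcorr_max", "xcorr_lag"),
                   family = "correlation", extended = FALSE))
}

# Spectral summary of a de-meaned, Hann-tapered window. DC is excluded by
# the de-meaning; the dominant frequency is searched over positive bins only.
spectral_features <- function(x, fs) {
  n <- length(x)
  xc <- x - mean(x)
  if (all(xc == 0)) {
    return(c(spec_energy = 0, dom_freq = 0, dom_mag = 0, spec_entropy = 0))
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  X <- stats::fft(xc * w)
  m <- floor(n / 2)
  pw <- (Mod(X[2:(m + 1)]))^2
  freqs <- (1:m) * fs / n
  tot <- sum(pw)
  p <- pw / tot
  ent <- if (m > 1) -sum(ifelse(p > 0, p * log(p), 0)) / log(m) else 0
  k <- which.max(pw)
  c(spec_energy = tot / n, dom_freq = freqs[k], dom_mag = sqrt(pw[k]) / n,
    spec_entropy = ent)
}

# First autocorrelation peak height at positive lag (0 when no peak exists).
autocorr_peak <- function(x, fs) {
  n <- length(x)
  if (stats::var(x) == 0) return(0)
  lag_max <- min(n - 1, as.integer(2 * fs))
  a <- as.numeric(acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf)[-1]
  pk <- find_peaks(a, min_prominence = 0.01, min_separation = 1)
  if (!length(pk)) 0 else a[pk[1]]
}

axis_features <- function(x, fs) {
  sdx <- sd(x)
  pk <- find_peaks(x, min_prominence = 0.1 * sdx,
                   min_separation = max(1, round(0.25 * fs)))
  sp <- spectral_features(x, fs)
  c(mean = mean(x), sd = sdx, n_peaks = length(pk),
    range = diff(range(x)), rms = sqrt(mean(x^2)),
    iqr = IQR(x), sp["spec_energy"], sp["dom_freq"], sp["dom_mag"],
    sp["spec_entropy"], autocorr_peak = autocorr_peak(x, fs))
}

cross_features <- function(v, ap, fs) {
  if (sd(v) == 0 || sd(ap) == 0) {
    return(c(xcorr_max = 0, xcorr_lag = 0))
  }
  lag_max <- min(length(v) - 1, as.integer(fs))   # gait-relevant lags: +/- 1 s
  cc <- ccf(v, ap, lag.max = lag_max, plot = FALSE, demean = TRUE)
  i <- which.max(as.numeric(cc$acf))
  c(xcorr_max = as.numeric(cc$acf[i]), xcorr_lag = as.numeric(cc$lag[i]) / fs)
}

#' Extract the per-window feature vector
#'
#' Computes the full registry of time-domain, frequency-domain and
#' correlation features from the sign-corrected vertical and anteroposterior
#' channels of one window. Peak counting uses a prominence of 0.1 x the
#' window SD and a 0.25 s minimum separation (a 4 steps/s ceiling, above the
#' ~3 Hz gait fundamental). Spectra are computed on the de-meaned,
#' Hann-tapered window; the dominant frequency excludes DC.
#'
#' @param v Vertical-axis samples (m/s^2), sign-corrected.
#' @param ap Anteroposterior-axis samples (m/s^2).
#' @param sample_rate Sampling rate, Hz.
#' @return Named numeric vector in [feature_registry()] order.
#' @export
extract_features <- function(v, ap, sample_rate) {
  if (length(v) < 2 || length(ap) != length(v)) {
    abort_adlsteps("window must have >= 2 samples on both channels", "adlsteps_feature_error")
  }
  if (anyNA(v) || anyNA(ap) || any(!is.finite(v)) || any(!is.finite(ap))) {
    abort_adlsteps("non-finite values in window; no silent imputation", "adlsteps_feature_error")
  }
  out <- c(axis_features(v, sample_rate), axis_features(ap, sample_rate),
           cross_features(v, ap, sample_rate))
  names(out) <- feature_registry()$name
  out
}

#' Build the windowed feature dataset for one configuration
#'
#' For every subject in a cohort: assigns axes on the unfiltered recording at
#' `location` (gravity defines vertical), applies the filter band, segments
#' into 50%-overlap windows of `window_length`, and extracts features for
#' every valid window.
#'
#' @param cohort An `adl_cohort`.
#' @param location Sensor location tag.
#' @param band Filter band name or [filter_band()].
#' @param window_length Window length in seconds.
#' @return data.frame with `subject_id`, `start`, `end`, `true_step_count`
#'   and one column per registry feature.
#' @export
build_feature_dataset <- function(cohort, location, band, window_length) {
  stopifnot(inherits(cohort, "adl_cohort"))
  if (is.character(band)) band <- filter_band(band)
  reg <- feature_registry()$name
  rows <- lapply(cohort, function(subj) {
    rec <- subj$recordings[[location]]
    if (is.null(rec)) {
      abort_adlsteps(paste0("cohort has no recording at location ", location),
                     "adlsteps_feature_error")
    }
    axes <- assign_axes(rec)
    filt <- apply_filter(rec, band)
    ch <- oriented_channels(filt, axes)
    win <- make_windows(rec, subj$annotations, window_length)
    win <- win[win$valid, , drop = FALSE]
    if (!nrow(win)) return(NULL)
    fs <- rec$sample_rate
    feats <- t(vapply(seq_len(nrow(win)), function(i) {
      i0 <- as.integer(round(win$start[i] * fs)) + 1L
      i1 <- as.integer(round(win$end[i] * fs))
      extract_features(ch$v[i0:i1], ch$ap[i0:i1], fs)
    }, numeric(length(reg))))
    cbind(win[c("subject_id", "start", "end", "true_step_count")],
          as.data.frame(feats))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a feature matrix to delimited text
#'
#' One row per valid window; columns are the registry features plus
#' `subject_id` and `true_step_count`.
#'
#' @param dataset Output of [build_feature_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_dataset <- function(dataset, path) {
  write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
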