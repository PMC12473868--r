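#' Mean absolute percentage error of step totals
#'
#' Per subject: `100 * |predicted - true| / true`. Because small-sample MAPE
#' distributions are skewed, the summary reported downstream is the median
#' and interquartile range (Q3 - Q1); the mean is also returned.
#'
#' @param true_totals Positive true step totals.
#' @param predicted_totals Predicted totals (same length).
#' @return List with `values` (per subject, %), `median`, `iqr`, `mean`.
#' @export
mape <- function(true_totals, predicted_totals) {
  stopifnot(length(true_totals) == length(predicted_totals))
  if (any(true_totals <= 0)) {
    abort_adlsteps("true totals must be positive for MAPE", "adlsteps_eval_error")
  }
  v <- 100 * abs(predicted_totals - true_totals) / true_totals
  list(values = v, median = median(v), iqr = IQR(v), mean = mean(v))
}

#' Percentage of true steps detected
#'
#' @param true_totals Positive true step totals.
#' @param predicted_totals Predicted totals.
#' @return List with `values` (`100 * predicted / true`), `median`, `iqr`.
#' @export
pct_detected <- function(true_totals, predicted_totals) {
  if (any(true_totals <= 0)) {
    abort_adlsteps("true totals must be positive", "adlsteps_eval_error")
  }
  v <- 100 * predicted_totals / true_totals
  list(values = v, median = median(v), iqr = IQR(v))
}

#' Inter-annotator agreement on windowed step counts
#'
#' Compares a second annotator's per-window counts against the first
#' annotator's ground truth on an aligned window grid: MAPE of the aggregated
#' (total) counts, and the Pearson correlation of the per-window counts.
#'
#' @param counts_a Ground-truth per-window counts (annotator A).
#' @param counts_b Second annotator's per-window counts, same grid.
#' @return List with `mape` (%), `pearson_r`, and `degenerate` (TRUE when a
#'   zero-variance series makes the correlation undefined).
#' @export
annotator_agreement <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b), length(counts_a) >= 2)
  tot_a <- sum(counts_a)
  if (tot_a <= 0) abort_adlsteps("annotator A total must be positive", "adlsteps_eval_error")
  m <- 100 * abs(sum(counts_b) - tot_a) / tot_a
  degenerate <- sd(counts_a) == 0 || sd(counts_b) == 0
  r <- if (degenerate) NA_real_ else cor(counts_a, counts_b)
  list(mape = m, pearson_r = r, degenerate = degenerate)
}

#' Friedman test across algorithms
#'
#' Rank-based comparison of algorithm errors over subjects (rows = subjects,
#' columns = algorithms; ties mid-ranked).
#'
#' @param error_matrix Numeric matrix, subjects x algorithms.
#' @return List with `statistic`, `p_value`, `degenerate` (all rows tied).
#' @export
friedman_compare <- function(error_matrix) {
  m <- as.matrix(error_matrix)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort_adlsteps("need >= 2 subjects and >= 2 algorithms", "adlsteps_eval_error")
  }
  degenerate <- all(apply(m, 1, function(r) length(unique(r)) == 1))
  if (degenerate) {
    return(list(statistic = 0, p_value = 1, degenerate = TRUE))
  }
  ft <- friedman.test(m)
  list(statistic = unname(ft$statistic), p_value = ft$p.value, degenerate = FALSE)
}

#' Normality gate for the algorithm comparison
#'
#' Shapiro-Wilk test plus Q-Q coordinates for visual assessment. The
#' decision is `"nonparametric"` when the Shapiro-Wilk p-value is at or below
#' `alpha`, or when the caller overrides (e.g., a p-value just above the
#' threshold combined with visible Q-Q deviations).
#'
#' @param values Numeric sample (n >= 3, non-constant).
#' @param alpha Gate level (default 0.05).
#' @param override Optional `"parametric"` or `"nonparametric"` to force the
#'   decision.
#' @return List with `shapiro_p`, `qq` (data.frame of theoretical/sample
#'   quantiles), `decision`.
#' @export
normality_gate <- function(values, alpha = 0.05, override = NULL) {
  if (length(values) < 3) {
    abort_adlsteps("need at least 3 values for a normality check", "adlsteps_eval_error")
  }
  if (sd(values) == 0) {
    abort_adlsteps("constant values: normality check degenerate", "adlsteps_eval_error")
  }
  sw <- shapiro.test(values)
  qq <- qqnorm(values, plot.it = FALSE)
  decision <- if (!is.null(override)) {
    match.arg(override, c("parametric", "nonparametric"))
  } else if (sw$p.value <= alpha) "nonparametric" else "parametric"
  list(shapiro_p = sw$p.value,
       qq = data.frame(theoretical = qq$x, sample = qq$y),
       decision = decision)
}

#' Smallest achievable two-sided exact sign-rank p-value
#'
#' With `n` paired differences, the most extreme Wilcoxon signed-rank outcome
#' (all differences sharing one sign, extreme rank ordering) has two-sided
#' exact p-value `2 * 0.5^n`; with few subjects this floor can exceed a
#' multiple-comparison-corrected significance level, making post hoc pairwise
#' tests uninformative.
#'
#' @param n Number of paired differences (>= 1).
#' @return The minimum two-sided exact p-value (capped at 1).
#' @export
wilcoxon_min_p <- function(n) {
  stopifnot(n >= 1)
  pmin(1, 2 * 0.5^n)
}

#' Overall step rate from a step total and duration
#'
#' @param steps Step count.
#' @param duration_s Duration in seconds.
#' @return Steps per second.
#' @export
step_rate <- function(steps, duration_s) {
  stopifnot(duration_s > 0)
  steps / duration_s
}

#' Convert a percentage error to a step-rate error
#'
#' Expresses a MAPE on step totals as an absolute error rate in steps/s at a
#' given underlying step frequency, making errors comparable across contexts
#' with very different walking intensities.
#'
#' @param mape_pct Percentage error.
#' @param rate Underlying step rate, steps/s.
#' @return Error in steps/s.
#' @export
mape_rate_error <- function(mape_pct, rate) {
  (mape_pct / 100) * rate
}

#' Compare step-counting algorithms on a common cohort
#'
#' Builds the per-subject x algorithm comparison table (predicted and true
#' totals, percent detected, MAPE contribution), per-algorithm medians and
#' IQRs, the normality gate on per-subject errors, and the Friedman test
#' across algorithms. Post hoc pairwise sign-rank tests are not computed
#' here: with n subjects the exact p-value floor is [wilcoxon_min_p()] and
#' small cohorts cannot survive multiplicity correction.
#'
#' @param predictions Named list: algorithm -> numeric vector of predicted
#'   totals, all aligned to `true_totals`'s subjects.
#' @param true_totals Positive true totals, one per subject.
#' @param subject_ids Optional subject identifiers.
#' @return List of class `algo_comparison` with `per_subject` (long
#'   data.frame), `summary` (per algorithm), `friedman`, `normality`.
#' @export
compare_algorithms <- function(predictions, true_totals, subject_ids = NULL) {
  stopifnot(is.list(predictions), length(predictions) >= 1)
  n <- length(true_totals)
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(n))
  per <- do.call(rbind, lapply(names(predictions), function(a) {
    p <- predictions[[a]]
    stopifnot(length(p) == n)
    data.frame(subject_id = subject_ids, algorithm = a,
               predicted_total = p, true_total = true_totals,
               pct_detected = 100 * p / true_totals,
               mape_contrib = 100 * abs(p - true_totals) / true_totals)
  }))
  summ <- do.call(rbind, lapply(names(predictions), function(a) {
    s <- per[per$algorithm == a, ]
    data.frame(algorithm = a,
               median_mape = median(s$mape_contrib), iqr_mape = IQR(s$mape_contrib),
               mean_mape = mean(s$mape_contrib),
               median_pct_detected = median(s$pct_detected),
               iqr_pct_detected = IQR(s$pct_detected))
  }))
  mat <- sapply(predictions, function(p) 100 * abs(p - true_totals) / true_totals)
  fr <- if (length(predictions) >= 2) friedman_compare(mat) else NULL
  norm <- tryCatch(normality_gate(as.numeric(mat)), error = function(e) NULL)
  structure(list(per_subject = per, summary = summ, friedman = fr, normality = norm),
            class = "algo_comparison")
}

#' @export
print.algo_comparison <- function(x, ...) {
  cat("<algo_comparison>\n")
  s <- x$summary
  s[-1] <- lapply(s[-1], function(col) round(col, 1))
  print(s, row.names = FALSE)
  if (!is.null(x$friedman)) {
    cat(sprintf("Friedman chi-squared = %.3g, p = %.4g%s\n",
                x$friedman$statistic, x$friedman$p_value,
                if (x$friedman$degenerate) " (degenerate)" else ""))
  }
  invisible(x)
}

#' Export an algorithm comparison report
#'
#' Writes the per-algorithm summary as delimited text and the full
#' comparison (including per-subject rows and test results) as JSON.
#'
#' @param comparison An `algo_comparison`.
#' @param csv_path Summary CSV path.
#' @param json_path Optional JSON path for the machine-readable report.
#' @return `csv_path`, invisibly.
#' @export
write_comparison <- function(comparison, csv_path, json_path = NULL) {
  stopifnot(inherits(comparison, "algo_comparison"))
  write.csv(comparison$summary, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      summary = comparison$summary,
      per_subject = comparison$per_subject,
      friedman = comparison$friedman,
      normality = list(shapiro_p = comparison$normality$shapiro_p,
                       decision = comparison$normality$decision)
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
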