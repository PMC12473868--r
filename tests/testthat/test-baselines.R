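pulse_rec <- function(peaks, amp = 0.5, dur = 20, fs = 100) {
  n <- dur * fs
  t <- (0:(n - 1)) / fs
  v <- rep(standard_gravity(), n)
  for (tp in peaks) {
    idx <- which(t >= tp & t < tp + 0.1)
    v[idx] <- v[idx] + amp * sin(pi * (t[idx] - tp) / 0.1)
  }
  make_rec(rep(0, n), rep(0, n), v)
}

test_that("threshold crossing counts pulses above threshold, none at rest", {
  flat <- make_rec(rep(0, 1000), rep(0, 1000), rep(standard_gravity(), 1000))
  expect_equal(tca_count(flat)$total, 0)

  five <- pulse_rec(c(2, 5, 8, 11, 14), amp = 0.5)
  res <- tca_count(five)
  expect_equal(res$total, 5)
  expect_equal(res$event_times, c(2, 5, 8, 11, 14), tolerance = 0.1)

  weak <- pulse_rec(c(2, 5, 8), amp = 0.2)   # below the 0.3 m/s^2 threshold
  expect_equal(tca_count(weak)$total, 0)
})

test_that("the refractory period suppresses rapid double crossings", {
  close_pair <- pulse_rec(c(5, 5.1, 8), amp = 0.5)
  expect_equal(tca_count(close_pair)$total, 2)
  expect_equal(tca_count(close_pair, tca_params(refractory = 0))$total, 3)
})

test_that("TCA counts are monotone non-increasing in the threshold", {
  set.seed(12)
  for (rep_i in 1:5) {
    peaks <- sort(runif(15, 1, 18))
    amps <- runif(15, 0.1, 1.2)
    n <- 2000
    t <- (0:(n - 1)) / 100
    v <- rep(standard_gravity(), n)
    for (j in seq_along(peaks)) {
      idx <- which(t >= peaks[j] & t < peaks[j] + 0.1)
      v[idx] <- v[idx] + amps[j] * sin(pi * (t[idx] - peaks[j]) / 0.1)
    }
    rec <- make_rec(rep(0, n), rep(0, n), v)
    counts <- vapply(seq(0.05, 1.2, by = 0.05), function(thr) {
      tca_count(rec, tca_params(threshold = thr))$total
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the wavelet counter recovers sinusoid cycle counts within 1", {
  fs <- 100
  for (f in c(0.8, 1.8, 2.5)) {
    dur <- 20
    t <- (0:(dur * fs - 1)) / fs
    rec <- make_rec(rep(0, length(t)), rep(0, length(t)),
                    standard_gravity() + sin(2 * pi * f * t))
    res <- cwt_count(rec)
    expect_lte(abs(res$total - f * dur), 1)
    expect_lt(max(abs(res$segment_freqs - f)) / f, 0.15)
  }
})

test_that("the wavelet counter stays silent on the noise floor", {
  set.seed(3)
  n <- 2000
  rec <- make_rec(rnorm(n, 0, 0.03), rnorm(n, 0, 0.03),
                  standard_gravity() + rnorm(n, 0, 0.03))
  expect_equal(cwt_count(rec)$total, 0)
})

test_that("the dominant wavelet scale adapts between bouts of different speed", {
  fs <- 100
  t1 <- (0:(10 * fs - 1)) / fs
  t2 <- (0:(10 * fs - 1)) / fs
  v <- c(sin(2 * pi * 1.0 * t1), sin(2 * pi * 2.0 * t2))
  rec <- make_rec(rep(0, length(v)), rep(0, length(v)), standard_gravity() + v)
  res <- cwt_count(rec)
  segs <- res$segment_freqs
  expect_lt(max(abs(segs[1:2] - 1.0)), 0.2)
  expect_lt(max(abs(segs[3:4] - 2.0)), 0.4)
  expect_lte(abs(res$total - (10 * 1 + 10 * 2)), 2)
})

test_that("recordings shorter than the wavelet support are refused", {
  rec <- make_rec(rnorm(300), rnorm(300), standard_gravity() + rnorm(300))
  expect_error(cwt_count(rec), "wavelet support")
})

test_that("external counters fail loudly and custom counters can be registered", {
  rec <- pulse_rec(c(2, 5), amp = 0.5)
  expect_error(count_steps("skdh", rec), class = "adlsteps_external_unavailable")
  expect_error(count_steps("oxw", rec), class = "adlsteps_external_unavailable")
  expect_error(count_steps("nope", rec), class = "adlsteps_unknown_counter")

  reg <- step_counters()
  expect_true(all(c("tca", "cwt", "skdh", "oxw") %in% reg$name))
  expect_false(reg$available[reg$name == "skdh"])

  register_step_counter("always42", function(rec, ...) {
    list(total = 42L, event_times = numeric(0))
  }, description = "test stub")
  expect_true("always42" %in% step_counters()$name)
  expect_equal(count_steps("always42", rec)$total, 42L)

  register_step_counter("broken", function(rec, ...) list(total = -1))
  expect_error(count_steps("broken", rec), class = "adlsteps_counter_contract")
})

test_that("both baselines are deterministic", {
  sess <- simulate_session(subject_profile("A", seed = 31),
                           session_spec(60, locations = "waist"))
  rec <- sess$recordings$waist
  expect_identical(tca_count(rec), tca_count(rec))
  expect_identical(cwt_count(rec), cwt_count(rec))
})
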