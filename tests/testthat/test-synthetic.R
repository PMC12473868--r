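test_that("a single constant-cadence bout lays down exactly the annotated steps", {
  p <- single_bout_profile(cadence = 1, dur = 10)
  sess <- simulate_session(p, session_spec(10, locations = c("ankle", "waist")))
  ev <- sess$annotations$events
  # steps at 0.5, 1.5, ..., 9.5 s: one per cadence period, half a period in
  expect_equal(nrow(ev), 10)
  expect_true(all(ev$event_type == "walking"))
  expect_equal(ev$time_s, seq(0.5, 9.5, by = 1), tolerance = 1e-8)
  # annotations are location-independent; every location shares the time base
  expect_identical(sess$recordings$ankle$time, sess$recordings$waist$time)
})

test_that("identical profile, spec and seed give bit-identical output", {
  p <- subject_profile("B", seed = 42)
  spec <- session_spec(30, locations = c("waist", "wrist_l"))
  expect_identical(simulate_session(p, spec), simulate_session(p, spec))
})

test_that("per-location streams are independent of the location subset", {
  p <- subject_profile("B", seed = 42)
  all3 <- simulate_session(p, session_spec(20, locations = c("waist", "ankle", "chest")))
  only1 <- simulate_session(p, session_spec(20, locations = "ankle"))
  expect_identical(all3$recordings$ankle, only1$recordings$ankle)
})

test_that("cohort construction validates profiles", {
  spec <- session_spec(10, locations = "waist")
  expect_error(simulate_cohort(list(), spec), "empty")
  expect_error(simulate_cohort(list(single_bout_profile("A")), spec), "at least 2")
  dup <- list(single_bout_profile("A"), single_bout_profile("A"))
  expect_error(simulate_cohort(dup, spec), "duplicate")
  ok <- simulate_cohort(list(single_bout_profile("A"), single_bout_profile("B")), spec)
  expect_length(ok, 2)
  expect_setequal(names(ok), c("A", "B"))
})

test_that("invalid profiles and specs are rejected with explanations", {
  expect_error(subject_profile("A", mean_cadence = 3.5), "mean_cadence")
  expect_error(subject_profile("A", shuffle_fraction = 1.2), "shuffle_fraction")
  expect_error(session_spec(-5), "positive")
  expect_error(session_spec(10, sample_rate = 0), "sample_rate")
  expect_error(session_spec(10, locations = "hip"), "unknown")
})

test_that("signals respect the sensor's physical envelope", {
  p <- subject_profile("C", adl_artifact_rate = 10, step_amplitude = 3, seed = 9)
  sess <- simulate_session(p, session_spec(60, locations = adl_locations()))
  lim <- 8 * standard_gravity()
  for (rec in sess$recordings) {
    expect_true(all(abs(rec$accel) <= lim + 1e-9))
  }
  # at rest the torso vertical mean is gravity (within 5%)
  quiet <- simulate_session(quiet_profile(), session_spec(60, locations = c("chest", "lower_back", "waist")))
  expect_equal(nrow(quiet$annotations$events), 0)
  for (rec in quiet$recordings) {
    ax <- assign_axes(rec)
    vbar <- mean(rec$accel[, ax$vertical_index] * ax$vertical_sign)
    expect_lt(abs(vbar - standard_gravity()) / standard_gravity(), 0.05)
  }
})

test_that("noiseless peak counting on the ankle vertical recovers the step count", {
  for (cad in c(0.6, 1.0, 1.6)) {
    p <- single_bout_profile("A", cadence = cad, dur = 20, seed = 11)
    sess <- simulate_session(p, session_spec(20, locations = "ankle"))
    rec <- sess$recordings$ankle
    ax <- assign_axes(rec)
    v <- adlsteps::oriented_channels(rec, ax)$v
    pk <- find_peaks(v - mean(v), min_prominence = 0.3 * sd(v),
                     min_separation = round(0.25 * rec$sample_rate))
    expect_equal(length(pk), nrow(sess$annotations$events))
  }
})

test_that("the default cohort realizes the target activity level", {
  dur <- 35 * 60
  cohort <- simulate_cohort(default_cohort_profiles(7, master_seed = 4),
                            session_spec(dur, locations = "waist"))
  rate <- cohort_step_rate(cohort, dur)
  expect_lt(abs(rate - 0.37) / 0.37, 0.10)
  totals <- vapply(cohort, function(s) nrow(s$annotations$events), numeric(1))
  expect_lt(abs(mean(totals) - 775), 2 * 301)
  expect_gt(sd(totals), 50)   # heterogeneous subjects, not clones
})
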