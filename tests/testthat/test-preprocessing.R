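test_that("axis assignment finds gravity and the correlated companion axis", {
  n <- 1000
  g <- 9.81
  rec <- make_rec(rep(0, n), rep(0, n), rep(g, n))
  ax <- assign_axes(rec)
  expect_equal(ax$vertical_index, 3)
  expect_equal(ax$vertical_sign, 1)

  rec_flip <- make_rec(rep(0, n), rep(0, n), rep(-g, n))
  expect_equal(assign_axes(rec_flip)$vertical_sign, -1)

  set.seed(1)
  v_dyn <- sin(2 * pi * 1 * (1:n) / 100)
  rec2 <- make_rec(v_dyn + rnorm(n, 0, 0.05), rnorm(n, 0, 0.5), g + v_dyn)
  ax2 <- assign_axes(rec2)
  expect_equal(ax2$vertical_index, 3)
  expect_equal(ax2$anteroposterior_index, 1)   # channel 1 tracks the vertical
})

test_that("axis assignment is invariant to axis permutations and flips", {
  sess <- simulate_session(subject_profile("A", seed = 8),
                           session_spec(20, locations = "waist"))
  rec <- sess$recordings$waist
  v_ref <- oriented_channels(rec, assign_axes(rec))$v
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))
  signs <- list(c(1, 1, 1), c(-1, 1, -1), c(1, -1, 1))
  for (pm in perms) for (sg in signs) {
    rot <- rec
    rot$accel <- sweep(rec$accel[, pm, drop = FALSE], 2, sg, "*")
    colnames(rot$accel) <- c("ax", "ay", "az")
    v_rot <- oriented_channels(rot, assign_axes(rot))$v
    expect_equal(v_rot, v_ref)
  }
})

test_that("degenerate constant channels fall back deterministically", {
  rec <- make_rec(rep(0, 100), rep(0, 100), rep(9.8, 100))
  ax <- assign_axes(rec)
  expect_equal(ax$anteroposterior_index, 1)   # lowest-index non-vertical channel
})

test_that("band-pass rejects DC and has the designed pass/stop gains", {
  n <- 2000
  const <- make_rec(rep(9.81, n), rep(0, n), rep(0, n))
  filt <- apply_filter(const, "narrow")
  # ~80 dB DC rejection relative to the 9.81 m/s^2 input
  expect_lt(max(abs(filt$accel[500:1500, 1])), 1e-3)

  # wide band is a low-pass: DC is preserved
  wide <- apply_filter(const, "wide")
  expect_equal(wide$accel[500:1500, 1], rep(9.81, 1001), tolerance = 1e-6)

  in_band <- apply_filter(sine_rec(2, dur = 20), "narrow")
  expect_lt(abs(max(abs(in_band$accel[500:1500, 1])) - 1), 0.05)
  stop_band <- apply_filter(sine_rec(10, dur = 20), "narrow")
  expect_lt(max(abs(stop_band$accel[500:1500, 1])), 0.05)
})

test_that("forward-backward filtering has zero phase lag", {
  rec <- sine_rec(2, dur = 20)
  filt <- apply_filter(rec, "narrow")
  x <- rec$accel[500:1500, 1]
  y <- filt$accel[500:1500, 1]
  cc <- ccf(y, x, lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filtering validates inputs", {
  short <- make_rec(rnorm(20), rnorm(20), rnorm(20))
  expect_error(apply_filter(short, "narrow"), "too short")
  slow <- make_rec(rnorm(500), rnorm(500), rnorm(500), fs = 20)
  expect_error(apply_filter(slow, "wide"), "twice")
})

test_that("window grids, labels and exclusion flags match the conventions", {
  rec <- make_rec(rep(0, 1000), rep(0, 1000), rep(9.8, 1000))  # 10 s @ 100 Hz
  ann <- annotations_of(c(1.0, 2.0, 7.0))
  win <- make_windows(rec, ann, 5)
  expect_equal(win$start, c(0, 2.5, 5))
  expect_equal(win$true_step_count[1], 2)       # events in [0, 5)
  expect_true(all(win$valid))

  # boundary event belongs to the later window (half-open intervals);
  # visible with non-overlapping windows where boundaries are shared
  ann_b <- annotations_of(c(5.0))
  win_b <- make_windows(rec, ann_b, 5, overlap = 0)
  expect_equal(win_b$true_step_count, c(0L, 1L))

  ann_ex <- annotations_of(c(1.0, 2.0, 7.0),
                           excluded = data.frame(start_s = 4, end_s = 6))
  win_ex <- make_windows(rec, ann_ex, 5)
  expect_equal(win_ex$valid, c(FALSE, FALSE, FALSE))  # all intersect [4,6]

  short_rec <- make_rec(rep(0, 100), rep(0, 100), rep(9.8, 100))
  expect_equal(nrow(make_windows(short_rec, ann, 5)), 0)
})

test_that("window labels conserve event totals", {
  set.seed(21)
  for (rep_i in 1:10) {
    dur <- sample(c(10, 20, 30), 1)
    rec <- make_rec(rep(0, dur * 100), 0, 9.8)
    ev <- sort(runif(sample(5:40, 1), 0, dur))
    ann <- annotations_of(ev)
    wl <- sample(c(2, 5), 1)

    # non-overlapping windows tile the recording: counts conserve the total
    win0 <- make_windows(rec, ann, wl, overlap = 0)
    in_cover <- sum(ev < max(win0$end))
    expect_equal(sum(win0$true_step_count), in_cover)

    # brute-force oracle for each 50%-overlap window label
    win <- make_windows(rec, ann, wl)
    brute <- vapply(seq_len(nrow(win)), function(i) {
      sum(ev >= win$start[i] & ev < win$end[i])
    }, numeric(1))
    expect_equal(win$true_step_count, as.integer(brute))

    # with 50% overlap interior events are counted exactly twice
    first_half <- sum(ev < win$start[1] + wl / 2)
    last_half <- sum(ev >= win$end[nrow(win)] - wl / 2 & ev < win$end[nrow(win)])
    beyond <- sum(ev >= win$end[nrow(win)])
    expect_equal(sum(win$true_step_count),
                 2 * (nrow(ann$events) - beyond) - first_half - last_half)
  }
})
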