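test_that("MAPE arithmetic and summaries", {
  expect_equal(mape(c(100, 200), c(100, 200))$median, 0)
  m <- mape(c(100, 200), c(90, 220))
  expect_equal(m$values, c(10, 10))
  expect_equal(m$median, 10)
  expect_error(mape(c(0, 10), c(1, 9)), "positive")
  # scale invariance
  m2 <- mape(7 * c(100, 200), 7 * c(90, 220))
  expect_equal(m2$values, m$values)
})

test_that("universal undercounting links MAPE and percent detected exactly", {
  true <- c(443, 600, 775, 801, 900, 1000, 1156)
  pred <- true * c(0.80, 0.83, 0.864, 0.864, 0.90, 0.95, 0.864)
  cmp <- compare_algorithms(list(alg = pred), true)
  s <- cmp$summary
  expect_equal(s$median_mape + s$median_pct_detected, 100)
  expect_equal(s$median_pct_detected, 86.4)
  expect_equal(s$median_mape, 13.6)
})

test_that("annotator agreement compares totals and per-window correlation", {
  a <- c(2, 0, 3, 1, 4, 0, 2)
  expect_equal(annotator_agreement(a, a)$mape, 0)
  expect_equal(annotator_agreement(a, a)$pearson_r, 1)

  b <- a + 1    # affine shift: perfect correlation, non-zero MAPE
  ag <- annotator_agreement(a, b)
  expect_equal(ag$pearson_r, 1)
  expect_gt(ag$mape, 0)

  # direct covariance-ratio oracle
  set.seed(9)
  bp <- sample(a)
  r_oracle <- sum((a - mean(a)) * (bp - mean(bp))) /
    sqrt(sum((a - mean(a))^2) * sum((bp - mean(bp))^2))
  expect_equal(annotator_agreement(a, bp)$pearson_r, r_oracle)

  expect_true(annotator_agreement(rep(2, 5), c(1, 2, 3, 2, 2))$degenerate)
})

test_that("Friedman comparison matches the rank formula and flags degeneracy", {
  # strict dominance over 7 subjects: ranks are 1 < 2 < 3 everywhere
  m <- cbind(a = 1:7, b = (1:7) + 10, c = (1:7) + 20)
  fr <- friedman_compare(m)
  # chi^2 = 12n/(k(k+1)) * sum (Rbar_j - (k+1)/2)^2 with n=7, k=3
  expect_equal(fr$statistic, 12 * 7 / (3 * 4) * ((1 - 2)^2 + 0 + (3 - 2)^2))
  expect_lt(fr$p_value, 0.05)

  same <- matrix(5, nrow = 4, ncol = 3)
  fr0 <- friedman_compare(same)
  expect_true(fr0$degenerate)
  expect_equal(fr0$statistic, 0)

  # 2x2: hand-computed ranks give chi^2 = n(=2) when the order is consistent
  m22 <- rbind(c(1, 2), c(3, 4))
  expect_equal(friedman_compare(m22)$statistic, 2)
  m22b <- rbind(c(1, 2), c(4, 3))   # opposite orders cancel
  expect_equal(friedman_compare(m22b)$statistic, 0)

  expect_error(friedman_compare(matrix(1:3, ncol = 1)), ">= 2")
})

test_that("Friedman agrees with an exact permutation oracle on tiny instances", {
  # all 2-subject, 3-algorithm instances with distinct values per row:
  # compare the statistic against brute-force enumeration of rank patterns
  rank_stat <- function(m) {
    R <- t(apply(m, 1, rank))
    n <- nrow(m); k <- ncol(m)
    12 * n / (k * (k + 1)) * sum((colMeans(R) - (k + 1) / 2)^2)
  }
  set.seed(2)
  for (i in 1:10) {
    m <- matrix(sample(1:100, 6), nrow = 2)
    expect_equal(friedman_compare(m)$statistic, rank_stat(m))
  }
})

test_that("the normality gate decides via Shapiro-Wilk with caller override", {
  x <- with(list(), { set.seed(14); rnorm(50) })
  g <- normality_gate(x)
  expect_gt(g$shapiro_p, 0.05)
  expect_equal(g$decision, "parametric")
  expect_equal(nrow(g$qq), 50)

  bimodal <- c(rnorm(25, -4, 0.3), rnorm(25, 4, 0.3))
  expect_equal(normality_gate(bimodal)$decision, "nonparametric")
  expect_lt(normality_gate(bimodal)$shapiro_p, 0.05)

  # borderline p with visible Q-Q deviation: caller can force nonparametric
  expect_equal(normality_gate(x, override = "nonparametric")$decision, "nonparametric")

  expect_error(normality_gate(rep(1, 10)), "constant")
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("the exact sign-rank floor matches enumeration", {
  expect_equal(wilcoxon_min_p(7), 0.015625)
  expect_equal(wilcoxon_min_p(1), 1)
  # oracle: all-positive differences put the statistic at its extreme value;
  # psignrank enumerates the exact null distribution
  for (n in c(5, 7, 10)) {
    expect_equal(wilcoxon_min_p(n), 2 * psignrank(0, n))
  }
  expect_equal(wilcoxon_min_p(10), 0.001953125)
})

test_that("rate conversions are plain arithmetic in the right units", {
  expect_equal(step_rate(775, 34.7 * 60), 0.3723, tolerance = 1e-3)
  expect_equal(mape_rate_error(13.6, 1.66), 0.22576)
  expect_equal(mape_rate_error(100, 2), 2)
})
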