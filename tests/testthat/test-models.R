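test_that("LOSO folds hold out each subject once and are reproducible", {
  ids <- sprintf("S%d", 1:7)
  folds <- loso_folds(ids, 7, seed = 1)
  expect_setequal(vapply(folds, `[[`, character(1), "test"), ids)
  for (f in folds) {
    expect_false(f$test %in% f$train)                    # no train/test overlap
    expect_setequal(c(f$train, f$test), ids)
  }
  f3a <- loso_folds(ids, 3, seed = 5)
  f3b <- loso_folds(ids, 3, seed = 5)
  expect_identical(f3a, f3b)
  expect_equal(length(unique(vapply(f3a, `[[`, character(1), "test"))), 3)
  expect_error(loso_folds(c("A", "B"), 3), "cannot exceed")
})

make_toy_dataset <- function(n_per = 30, subjects = c("A", "B", "C"), seed = 4) {
  set.seed(seed)
  reg <- feature_registry()$name
  rows <- lapply(subjects, function(id) {
    X <- matrix(rnorm(n_per * length(reg)), n_per)
    colnames(X) <- reg
    df <- as.data.frame(X)
    df$subject_id <- id
    # labels are a clean function of one feature, plus noise
    df$true_step_count <- pmax(0, round(2 + 1.5 * df$v_sd + rnorm(n_per, 0, 0.1)))
    df
  })
  do.call(rbind, rows)
}

test_that("scoring scales window RMSE to steps per second, median over folds", {
  ds <- make_toy_dataset()
  folds <- loso_folds(unique(ds$subject_id), 3, seed = 1)

  # a regressor that reproduces its labels exactly scores zero
  ds0 <- ds
  ds0$true_step_count <- 5L
  perfect <- function(X, y) { m <- y[1]; function(Xn) rep(m, nrow(Xn)) }
  sc0 <- train_and_score(ds0, perfect, 5, folds)
  expect_equal(sc0$rmse_per_s, 0)

  # constant mean predictor: fold RMSE has a closed form the test recomputes
  const <- function(X, y) { m <- mean(y); function(Xn) rep(m, nrow(Xn)) }
  sc <- train_and_score(ds, const, 5, folds)
  oracle <- vapply(folds, function(f) {
    ytr <- ds$true_step_count[ds$subject_id %in% f$train]
    yte <- ds$true_step_count[ds$subject_id == f$test]
    sqrt(mean((mean(ytr) - yte)^2)) / 5
  }, numeric(1))
  expect_equal(sc$fold_rmses, oracle)
  expect_equal(sc$rmse_per_s, median(oracle))
})

test_that("feature standardization uses training-fold statistics only", {
  ds <- make_toy_dataset()
  fcols <- adlsteps:::feature_columns(ds)
  tr <- ds$subject_id %in% c("A", "B")
  std <- adlsteps:::standardizer(as.matrix(ds[tr, fcols]))
  Z <- std(ds[ds$subject_id == "C", fcols])
  # held-out windows are centered with the TRAINING mean, so they are not
  # themselves mean-zero; re-standardizing with a different training set moves them
  expect_gt(max(abs(colMeans(Z))), 0.01)
  tr2 <- ds$subject_id %in% c("A", "C")
  std2 <- adlsteps:::standardizer(as.matrix(ds[tr2, fcols]))
  expect_false(isTRUE(all.equal(std(ds[1:5, fcols]), std2(ds[1:5, fcols]))))
})

test_that("every named regressor trains, predicts, and is deterministic", {
  ds <- make_toy_dataset(n_per = 25)
  folds <- loso_folds(unique(ds$subject_id), 2, seed = 2)
  for (rg in regressor_names()) {
    s1 <- train_and_score(ds, rg, 2, folds, seed = 7)
    s2 <- train_and_score(ds, rg, 2, folds, seed = 7)
    expect_identical(s1, s2)
    expect_true(is.finite(s1$rmse_per_s) && s1$rmse_per_s >= 0)
  }
  expect_error(train_and_score(ds, "boost3000", 2, folds), "unknown regressor")
})

test_that("window predictions aggregate to unbiased subject totals", {
  expect_equal(aggregate_window_totals(c(2, 3, 4), overlap = 0), 9)
  expect_equal(aggregate_window_totals(rep(0, 10)), 0)
  expect_equal(aggregate_window_totals(c(-1, -2), overlap = 0), 0)  # clipped at 0
  W <- 40; p <- 2.5
  expect_equal(aggregate_window_totals(rep(p, W)), p * W / 2 + p / 2)
  expect_lt(abs(aggregate_window_totals(rep(p, W)) - p * W / 2) / (p * W / 2), 0.03)
})

test_that("the configuration grid is scored deterministically", {
  cohort <- small_cohort(3, dur = 90, seed = 6)
  grid <- make_config_grid("waist", c("wide", "narrow"), 5, "GB")
  s1 <- run_config_grid(cohort, grid, n_folds = 2, seed = 9)
  s2 <- run_config_grid(cohort, grid, n_folds = 2, seed = 9)
  expect_equal(nrow(s1), 2)
  expect_identical(s1$rmse_per_s, s2$rmse_per_s)
  expect_true(all(s1$rmse_per_s >= 0))
  expect_error(run_config_grid(cohort, grid, n_folds = 5), "smaller")
})

test_that("noisier features never help held-out accuracy, on average", {
  cohort <- small_cohort(4, dur = 90, seed = 3)
  ds <- build_feature_dataset(cohort, "waist", "narrow", 5)
  fcols <- adlsteps:::feature_columns(ds)
  folds <- loso_folds(unique(ds$subject_id), 4, seed = 1)
  base <- train_and_score(ds, "kNN", 5, folds)$rmse_per_s
  noisy_scores <- vapply(1:3, function(i) {
    dn <- ds
    set.seed(100 + i)
    dn[fcols] <- dn[fcols] + matrix(rnorm(nrow(dn) * length(fcols), 0, 5), nrow(dn))
    train_and_score(dn, "kNN", 5, folds)$rmse_per_s
  }, numeric(1))
  expect_gt(mean(noisy_scores), base)
})
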