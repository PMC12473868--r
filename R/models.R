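#' The five window-level step-count regressor types
#'
#' Gradient boosting (GB), k-nearest neighbours (kNN), multilayer perceptron
#' (MLP), random forest (RF) and support vector regression (SVR), each
#' mapping the per-window feature vector to the window's step count and
#' trained to minimize RMSE. Hyperparameters are fixed library defaults
#' (documented in [fit_step_regressor()]) so the comparison is about the
#' sensing/analysis configuration, not tuning.
#'
#' @return Character vector of regressor names.
#' @export
regressor_names <- function() c("GB", "kNN", "MLP", "RF", "SVR")

#' Fit one step-count regressor
#'
#' Features must already be standardized with training-fold statistics.
#' Fixed hyperparameters: GB = 150 boosting rounds, learning rate 0.1,
#' depth 3, single thread; kNN = k 5; MLP = one hidden layer of 10 units,
#' weight decay 1e-3, 300 iterations; RF = 300 trees; SVR = radial kernel
#' eps-regression defaults. Stochastic learners (GB tree building, MLP
#' initial weights, RF bootstrap) are seeded.
#'
#' @param name One of [regressor_names()], or a function
#'   `function(X, y) -> function(X_new) -> predictions` for custom/oracle
#'   regressors.
#' @param X Numeric feature matrix (rows = windows).
#' @param y Numeric step counts.
#' @param seed Integer seed.
#' @return A prediction function `function(X_new) -> numeric`.
#' @export
fit_step_regressor <- function(name, X, y, seed = 1L) {
  if (is.function(name)) return(name(X, y))
  X <- as.matrix(X)
  switch(name,
    GB = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      booster <- with_seed(seed, xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = 0.1, max_depth = 3,
                      nthread = 1),
        data = dtrain, nrounds = 150, verbose = 0
      ))
      function(Xn) predict(booster, xgboost::xgb.DMatrix(as.matrix(Xn)))
    },
    kNN = {
      fit <- caret::knnreg(X, y, k = 5)
      function(Xn) predict(fit, as.matrix(Xn))
    },
    MLP = {
      fit <- with_seed(seed, nnet::nnet(
        x = X, y = y, size = 10, linout = TRUE, decay = 1e-3,
        maxit = 300, trace = FALSE, MaxNWts = 10000
      ))
      function(Xn) as.numeric(predict(fit, as.matrix(Xn)))
    },
    RF = {
      fit <- with_seed(seed, randomForest::randomForest(x = X, y = y, ntree = 300))
      function(Xn) as.numeric(predict(fit, as.matrix(Xn)))
    },
    SVR = {
      fit <- e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial")
      function(Xn) as.numeric(predict(fit, as.matrix(Xn)))
    },
    abort_adlsteps(paste0("unknown regressor: ", name), "adlsteps_model_error")
  )
}

#' Leave-one-subject-out folds
#'
#' Each fold holds out exactly one subject, drawn without replacement with
#' the given seed. With `n_folds` equal to the number of subjects, every
#' subject is held out exactly once.
#'
#' @param subject_ids Character vector of unique subject IDs.
#' @param n_folds Number of folds (<= number of subjects).
#' @param seed Integer seed for the draw.
#' @return List of folds, each `list(train = ids, test = id)`.
#' @export
loso_folds <- function(subject_ids, n_folds = length(subject_ids), seed = 1L) {
  subject_ids <- unique(subject_ids)
  if (n_folds > length(subject_ids)) {
    abort_adlsteps("n_folds cannot exceed the number of subjects", "adlsteps_fold_error")
  }
  held_out <- with_seed(seed, sample(subject_ids, n_folds))
  lapply(held_out, function(id) list(train = setdiff(subject_ids, id), test = id))
}

# Column-wise standardization using training-fold statistics only
# (zero-variance columns pass through unscaled).
standardizer <- function(X_train) {
  mu <- colMeans(X_train)
  sdev <- apply(X_train, 2, sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  function(X) sweep(sweep(as.matrix(X), 2, mu), 2, sdev, "/")
}

feature_columns <- function(dataset) {
  intersect(feature_registry()$name, names(dataset))
}

#' Train and score one configuration under LOSO cross-validation
#'
#' For each fold: standardizes features with training-fold statistics, fits
#' the regressor on the training subjects' windows, predicts the held-out
#' subject's windows, computes the window-level RMSE in steps and divides by
#' the window length so configurations with different window lengths are
#' comparable (RMSE scaled to 1 s). The configuration score is the median
#' over folds.
#'
#' @param dataset Feature dataset from [build_feature_dataset()].
#' @param regressor Regressor name or factory function (see
#'   [fit_step_regressor()]).
#' @param window_length Window length in seconds (the scaling denominator).
#' @param folds Folds from [loso_folds()].
#' @param seed Integer seed passed to stochastic learners.
#' @return List of class `config_score` with `rmse_per_s` (median over
#'   folds) and `fold_rmses` (steps/s per fold).
#' @export
train_and_score <- function(dataset, regressor, window_length, folds, seed = 1L) {
  fcols <- feature_columns(dataset)
  fold_rmses <- vapply(folds, function(fold) {
    tr <- dataset$subject_id %in% fold$train
    te <- dataset$subject_id == fold$test
    if (!any(tr) || !any(te)) {
      abort_adlsteps("empty training or test fold", "adlsteps_model_error")
    }
    std <- standardizer(as.matrix(dataset[tr, fcols]))
    pred_fn <- fit_step_regressor(regressor, std(dataset[tr, fcols]),
                                  dataset$true_step_count[tr], seed = seed)
    preds <- pred_fn(std(dataset[te, fcols]))
    sqrt(mean((preds - dataset$true_step_count[te])^2)) / window_length
  }, numeric(1))
  structure(list(rmse_per_s = median(fold_rmses), fold_rmses = fold_rmses),
            class = "config_score")
}

#' Build a configuration grid
#'
#' @param locations,bands,windows,regressors Factor levels to cross.
#' @return data.frame with one row per configuration.
#' @export
make_config_grid <- function(locations = adl_locations(),
                             bands = filter_band_names(),
                             windows = c(0.5, 2, 5),
                             regressors = regressor_names()) {
  expand.grid(location = locations, filter = bands, window_length = windows,
              regressor = regressors, stringsAsFactors = FALSE)
}

#' Score every configuration in a grid
#'
#' Builds the feature dataset once per (location, filter, window) cell and
#' scores each regressor on it. Folds and learner seeds are derived
#' deterministically from `seed` and the configuration, so reruns reproduce
#' identical scores and each parameter combination draws its own held-out
#' subjects.
#'
#' @param cohort An `adl_cohort`.
#' @param grid Configuration grid from [make_config_grid()].
#' @param n_folds Number of LOSO folds per configuration.
#' @param seed Master seed.
#' @return data.frame of class `config_scores`: the grid plus `rmse_per_s`,
#'   with per-fold RMSEs in the `fold_rmses` attribute.
#' @export
run_config_grid <- function(cohort, grid, n_folds = 3, seed = 1L) {
  stopifnot(inherits(cohort, "adl_cohort"))
  ids <- names(cohort)
  if (length(ids) < n_folds) {
    abort_adlsteps("cohort smaller than n_folds", "adlsteps_fold_error")
  }
  grid$rmse_per_s <- NA_real_
  fold_list <- vector("list", nrow(grid))
  cells <- unique(grid[c("location", "filter", "window_length")])
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    dataset <- build_feature_dataset(cohort, cell$location, cell$filter,
                                     cell$window_length)
    rows <- which(grid$location == cell$location & grid$filter == cell$filter &
                    grid$window_length == cell$window_length)
    for (ri in rows) {
      key <- paste(grid$location[ri], grid$filter[ri], grid$window_length[ri],
                   grid$regressor[ri], sep = "|")
      cfg_seed <- derive_seed(seed, key)
      folds <- loso_folds(ids, n_folds, seed = cfg_seed)
      sc <- train_and_score(dataset, grid$regressor[ri], grid$window_length[ri],
                            folds, seed = cfg_seed)
      grid$rmse_per_s[ri] <- sc$rmse_per_s
      fold_list[[ri]] <- sc$fold_rmses
    }
  }
  attr(grid, "fold_rmses") <- fold_list
  class(grid) <- c("config_scores", class(grid))
  grid
}

#' Aggregate per-window predictions to a subject total
#'
#' Predictions are clipped at zero. With 50% overlap every time point is
#' covered by two windows, so the total is half the sum, plus a quarter of
#' the first and last window predictions to correct for the single-counted
#' half-windows at the recording edges (unbiased when predictions are
#' locally constant). With no overlap the total is the plain sum.
#'
#' @param preds Numeric window predictions, in window order.
#' @param overlap Overlap fraction used to build the windows (0 or 0.5).
#' @return Numeric total.
#' @export
aggregate_window_totals <- function(preds, overlap = 0.5) {
  preds <- pmax(preds, 0)
  if (!length(preds)) return(0)
  if (overlap == 0) return(sum(preds))
  if (overlap != 0.5) {
    abort_adlsteps("only 0 or 0.5 overlap supported", "adlsteps_model_error")
  }
  if (length(preds) == 1) return(preds)
  0.5 * sum(preds) + 0.25 * (preds[1] + preds[length(preds)])
}

#' Per-subject total-step predictions under full LOSO
#'
#' Runs a leave-one-subject-out loop over every subject: trains the regressor
#' on all other subjects and aggregates the held-out subject's window
#' predictions to a total with [aggregate_window_totals()].
#'
#' @param dataset Feature dataset from [build_feature_dataset()].
#' @param regressor Regressor name or factory.
#' @param seed Integer seed.
#' @return data.frame with `subject_id`, `predicted_total`, and
#'   `true_total_windows` (the same aggregation applied to the true window
#'   labels).
#' @export
loso_subject_totals <- function(dataset, regressor, seed = 1L) {
  ids <- unique(dataset$subject_id)
  folds <- loso_folds(ids, length(ids), seed = seed)
  fcols <- feature_columns(dataset)
  rows <- lapply(folds, function(fold) {
    tr <- dataset$subject_id %in% fold$train
    te <- dataset$subject_id == fold$test
    std <- standardizer(as.matrix(dataset[tr, fcols]))
    pred_fn <- fit_step_regressor(regressor, std(dataset[tr, fcols]),
                                  dataset$true_step_count[tr], seed = seed)
    preds <- pred_fn(std(dataset[te, fcols]))
    data.frame(subject_id = fold$test,
               predicted_total = aggregate_window_totals(preds),
               true_total_windows = aggregate_window_totals(dataset$true_step_count[te]))
  })
  out <- do.call(rbind, rows)
  out[order(out$subject_id), , drop = FALSE]
}
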