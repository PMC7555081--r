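#' Brain-age model hyperparameters
#'
#' Container for the prediction-engine settings. The default engine is
#' gradient-boosted regression trees (xgboost) with maximum depth 6, 140
#' estimators and learning rate 0.1 — the optimum found by the randomized
#' search the analysis prescribes. A plain linear least-squares engine sits
#' behind the same fit/predict contract; it is orders of magnitude faster
#' and is the engine the simulation-heavy checks use.
#'
#' @param engine `"xgboost"` or `"lm"`.
#' @param max_depth,n_estimators,learning_rate Tree-booster settings
#'   (ignored by the linear engine).
#' @param n_folds Folds for cross-validated prediction.
#' @param seed Seed used for fold assignment when folds are not supplied.
#' @return A list of class `"model_params"`.
#' @export
model_params <- function(engine = c("xgboost", "lm"), max_depth = 6,
                         n_estimators = 140, learning_rate = 0.1,
                         n_folds = 10, seed = 42) {
  engine <- match.arg(engine)
  stopifnot(max_depth >= 1, n_estimators >= 1, n_folds >= 2,
            learning_rate > 0, learning_rate <= 1)
  structure(
    list(engine = engine, max_depth = as.integer(max_depth),
         n_estimators = as.integer(n_estimators),
         learning_rate = learning_rate, n_folds = as.integer(n_folds),
         seed = as.integer(seed)),
    class = "model_params"
  )
}

feature_matrix <- function(features) {
  as.matrix(features[, setdiff(names(features), "participant_id"),
                     drop = FALSE])
}

#' Fit a brain-age model
#'
#' @param features Feature tibble (numeric columns; `participant_id`
#'   ignored).
#' @param age Chronological ages (years), one per row.
#' @param params [model_params()].
#' @return A `"brainage_fit"` usable with [predict()][stats::predict] and
#'   [permutation_importance()].
#' @export
fit_brainage <- function(features, age, params = model_params()) {
  X <- feature_matrix(features)
  stopifnot(nrow(X) == length(age))
  fit <- switch(
    params$engine,
    xgboost = xgboost::xgboost(
      x = X, y = age, max_depth = params$max_depth,
      nrounds = params$n_estimators, learning_rate = params$learning_rate,
      objective = "reg:squarederror", nthreads = 1, seed = params$seed,
      verbosity = 0
    ),
    lm = {
      Xi <- cbind(`(Intercept)` = 1, X)
      cf <- lm.fit(Xi, age)$coefficients
      cf[is.na(cf)] <- 0
      cf
    }
  )
  structure(list(engine = params$engine, fit = fit,
                 feature_names = colnames(X), params = params),
            class = "brainage_fit")
}

#' @export
predict.brainage_fit <- function(object, newdata, ...) {
  X <- feature_matrix(newdata)
  if (!identical(colnames(X), object$feature_names)) {
    if (!all(object$feature_names %in% colnames(X))) {
      abort("feature columns of `newdata` do not match the fitted model.")
    }
    X <- X[, object$feature_names, drop = FALSE]
  }
  if (nrow(X) == 0) return(numeric(0))
  switch(object$engine,
         xgboost = predict(object$fit, X),
         lm = as.numeric(cbind(1, X) %*% object$fit))
}

#' Seeded cross-validation fold assignment
#'
#' Uniform random partition of `n` participants into `k` folds. Reusing one
#' assignment across all feature sets of a run keeps the per-set brain-age
#' deltas comparable.
#'
#' @param n Number of participants.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(n, k = 10, seed = 42) {
  if (n < k) abort("cannot form more folds than participants.")
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Out-of-fold brain-age prediction
#'
#' Fits the model on each training fold and predicts the held-out fold, so
#' every participant receives exactly one prediction from a model that
#' never saw them. The brain-age delta is predicted minus chronological
#' age.
#'
#' @inheritParams fit_brainage
#' @param folds Optional fold assignment from [make_folds()]; by default a
#'   seeded assignment with `params$n_folds` folds.
#' @param feature_set Label recorded with the result.
#' @return A `"brainage_result"`: tibble with `participant_id`, `age`,
#'   `predicted_age`, `delta`, `fold`, `feature_set`.
#' @export
crossval_predict <- function(features, age, params = model_params(),
                             folds = NULL, feature_set = "features") {
  n <- nrow(features)
  stopifnot(n == length(age))
  if (is.null(folds)) folds <- make_folds(n, params$n_folds, params$seed)
  stopifnot(length(folds) == n)
  ids <- if ("participant_id" %in% names(features)) {
    features$participant_id
  } else {
    sprintf("P%06d", seq_len(n))
  }
  pred <- numeric(n)
  for (f in sort(unique(folds))) {
    test <- folds == f
    fit <- fit_brainage(features[!test, , drop = FALSE], age[!test], params)
    pred[test] <- predict(fit, features[test, , drop = FALSE])
  }
  structure(
    tibble(participant_id = ids, age = age, predicted_age = pred,
           delta = pred - age, fold = folds, feature_set = feature_set),
    class = c("brainage_result", "tbl_df", "tbl", "data.frame"),
    params = params
  )
}

#' Train on one sample, predict another
#'
#' Fits the model on the training participants only and returns one
#' prediction per test participant (a pointwise function of the test
#' features; no test information enters the fit).
#'
#' @param train_features,train_age Training data.
#' @param test_features Test features with the same columns.
#' @param params [model_params()].
#' @return Numeric vector of predicted ages, one per test row.
#' @export
fit_then_predict <- function(train_features, train_age, test_features,
                             params = model_params()) {
  fit <- fit_brainage(train_features, train_age, params)
  predict(fit, test_features)
}

#' Prediction accuracy metrics
#'
#' Pearson r (with Fisher-z 95\% CI), R\eqn{^2} computed as
#' 1 - SS\eqn{_{res}}/SS\eqn{_{tot}}, RMSE and MAE (years) of predicted
#' versus chronological age.
#'
#' @param result A `"brainage_result"` (or any tibble with `age` and
#'   `predicted_age`).
#' @return One-row tibble: `feature_set`, `n`, `r`, `r_lo`, `r_hi`, `r2`,
#'   `rmse`, `mae`.
#' @export
prediction_metrics <- function(result) {
  if (nrow(result) < 3) abort("need at least 3 predictions.")
  if (sd(result$age) == 0) abort("zero variance in chronological age.")
  err <- result$predicted_age - result$age
  r <- if (sd(result$predicted_age) == 0) {
    NA_real_  # constant predictions: correlation undefined, R^2 still is
  } else {
    cor(result$predicted_age, result$age)
  }
  z <- atanh(r)
  se <- 1 / sqrt(nrow(result) - 3)
  tibble(
    feature_set = if ("feature_set" %in% names(result)) {
      result$feature_set[1]
    } else {
      "features"
    },
    n = nrow(result),
    r = r,
    r_lo = tanh(z - qnorm(0.975) * se),
    r_hi = tanh(z + qnorm(0.975) * se),
    r2 = 1 - sum(err^2) / sum((result$age - mean(result$age))^2),
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err))
  )
}

#' Randomized hyperparameter search
#'
#' Samples candidates from the search space and scores each by
#' cross-validated mean absolute error on shared folds, returning the best
#' candidate as a [model_params()]. With 10 folds and 10 iterations this is
#' the tuning protocol of the emulated analysis; the default search space
#' scans depth 3-12, 60-220 trees in steps of 40, and learning rates
#' \{0.1, 0.01, 0.05\}.
#'
#' @inheritParams fit_brainage
#' @param search_space Named list with vectors `max_depth`, `n_estimators`,
#'   `learning_rate`.
#' @param n_folds,n_iterations Folds and sampled candidates.
#' @param seed Seed for candidate sampling and fold assignment.
#' @param engine Engine the candidates are evaluated with.
#' @return The winning `"model_params"`, with the scored candidates in
#'   attribute `"search"`.
#' @export
tune_params <- function(features, age,
                        search_space = list(
                          max_depth = 3:12,
                          n_estimators = seq(60, 220, by = 40),
                          learning_rate = c(0.1, 0.01, 0.05)
                        ),
                        n_folds = 10, n_iterations = 10, seed = 42,
                        engine = "xgboost") {
  n <- nrow(features)
  if (n < n_folds) abort("cannot form more folds than participants.")
  if (length(search_space) == 0) abort("empty search space.")
  grid <- expand.grid(search_space)
  set.seed(seed)
  take <- sample.int(nrow(grid), min(n_iterations, nrow(grid)))
  folds <- make_folds(n, n_folds, seed)
  scores <- purrr::map_dbl(take, function(i) {
    p <- model_params(engine = engine, max_depth = grid$max_depth[i],
                      n_estimators = grid$n_estimators[i],
                      learning_rate = grid$learning_rate[i],
                      n_folds = n_folds, seed = seed)
    res <- crossval_predict(features, age, p, folds = folds)
    mean(abs(res$predicted_age - res$age))
  })
  best <- take[which.min(scores)]
  out <- model_params(engine = engine, max_depth = grid$max_depth[best],
                      n_estimators = grid$n_estimators[best],
                      learning_rate = grid$learning_rate[best],
                      n_folds = n_folds, seed = seed)
  attr(out, "search") <- bind_cols(as_tibble(grid[take, , drop = FALSE]),
                                   tibble(cv_mae = scores))
  out
}

#' Permutation feature importance
#'
#' Mean increase in prediction MAE when a single feature column is randomly
#' shuffled, averaged over `n_repeats` shuffles; features the model ignores
#' score (close to) zero.
#'
#' @param fit A `"brainage_fit"`.
#' @param features,age Evaluation data.
#' @param n_repeats Shuffles per feature.
#' @param seed Seed making the shuffles reproducible.
#' @return Tibble `feature`, `importance`, `n_repeats`, sorted by
#'   decreasing importance.
#' @export
permutation_importance <- function(fit, features, age, n_repeats = 5,
                                   seed = 42) {
  stopifnot(inherits(fit, "brainage_fit"), n_repeats >= 1)
  set.seed(seed)
  base_mae <- mean(abs(predict(fit, features) - age))
  n <- nrow(features)
  imp <- purrr::map_dbl(fit$feature_names, function(fname) {
    drops <- purrr::map_dbl(seq_len(n_repeats), function(r) {
      shuffled <- features
      shuffled[[fname]] <- shuffled[[fname]][sample.int(n)]
      mean(abs(predict(fit, shuffled) - age)) - base_mae
    })
    mean(drops)
  })
  tibble(feature = fit$feature_names, importance = imp,
         n_repeats = n_repeats) %>%
    arrange(dplyr::desc(.data$importance))
}
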