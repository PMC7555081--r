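lm_params <- model_params(engine = "lm", n_folds = 5, seed = 41)

test_that("an uninformative constant feature predicts the fold mean age", {
  set.seed(42)
  feats <- tibble::tibble(flat = rep(3, 200))
  age <- runif(200, 45, 82)
  res <- crossval_predict(feats, age, lm_params)
  # each out-of-fold prediction equals its training fold's mean age
  for (f in unique(res$fold)) {
    expect_equal(unique(round(res$predicted_age[res$fold == f], 10)),
                 round(mean(age[res$fold != f]), 10))
  }
  expect_lte(prediction_metrics(res)$r2, 0.01)
})

test_that("a noise-free monotone age signal is learned by both engines", {
  set.seed(43)
  n <- 2000
  age <- runif(n, 45, 82)
  feats <- tibble::tibble(vol = 8000 - 25 * age + rnorm(n, sd = 1e-6))
  res_lm <- crossval_predict(feats, age, lm_params)
  expect_gt(cor(res_lm$predicted_age, res_lm$age), 0.95)

  xgb <- model_params(engine = "xgboost", n_estimators = 60, n_folds = 5,
                      seed = 43)
  res_xgb <- crossval_predict(feats, age, xgb)
  expect_gt(cor(res_xgb$predicted_age, res_xgb$age), 0.95)
})

test_that("permuted ages give out-of-fold R2 at chance", {
  sim <- small_sim(n = 600, seed = 44)
  rf <- residualize_features(average_hemispheres(sim$features), sim$cohort)
  set.seed(45)
  shuffled_age <- sample(sim$cohort$age)
  res <- crossval_predict(rf, shuffled_age, lm_params)
  expect_lte(prediction_metrics(res)$r2, 0.02)
})

test_that("every participant gets exactly one out-of-fold prediction and delta", {
  sim <- small_sim(n = 250, seed = 46)
  rf <- residualize_features(average_hemispheres(sim$features), sim$cohort)
  res <- crossval_predict(rf, sim$cohort$age, lm_params)
  expect_equal(nrow(res), 250)
  expect_equal(anyDuplicated(res$participant_id), 0)
  expect_equal(res$delta, res$predicted_age - res$age)
  expect_equal(sort(unique(res$fold)), 1:5)
  expect_error(crossval_predict(rf[1:3, ], sim$cohort$age[1:3],
                                model_params(engine = "lm", n_folds = 5)),
               "folds")
})

test_that("out-of-fold predictions equal a manual fit on each fold complement", {
  # CV hygiene: the model scoring fold f must be exactly the one trained
  # without fold f
  sim <- small_sim(n = 300, seed = 47)
  rf <- residualize_features(average_hemispheres(sim$features), sim$cohort)
  folds <- make_folds(300, 5, seed = 47)
  res <- crossval_predict(rf, sim$cohort$age, lm_params, folds = folds)
  for (f in 1:5) {
    manual <- fit_then_predict(rf[folds != f, ], sim$cohort$age[folds != f],
                               rf[folds == f, ], lm_params)
    expect_equal(res$predicted_age[folds == f], manual)
  }
})

test_that("fit_then_predict is a pointwise function of the test features", {
  sim <- small_sim(n = 400, seed = 48)
  rf <- residualize_features(average_hemispheres(sim$features), sim$cohort)
  train <- 1:300
  test <- 301:400
  pred <- fit_then_predict(rf[train, ], sim$cohort$age[train], rf[test, ],
                           lm_params)
  dup <- fit_then_predict(rf[train, ], sim$cohort$age[train],
                          rf[c(test, test), ], lm_params)
  expect_equal(dup, c(pred, pred))
  expect_length(fit_then_predict(rf[train, ], sim$cohort$age[train],
                                 rf[0, ], lm_params), 0)

  # train/test accuracy close to 10-fold CV accuracy on same-distribution data
  cv <- crossval_predict(rf[train, ], sim$cohort$age[train], lm_params)
  r_cv <- prediction_metrics(cv)$r
  r_test <- cor(pred, sim$cohort$age[test])
  expect_lt(abs(r_test - r_cv), 0.15)
})

test_that("prediction metrics match hand computation and limiting cases", {
  res <- tibble::tibble(age = c(50, 55, 60, 65, 70),
                        predicted_age = c(52, 54, 63, 62, 71))
  res$delta <- res$predicted_age - res$age
  m <- prediction_metrics(res)
  err <- res$predicted_age - res$age
  expect_equal(m$r, cor(res$predicted_age, res$age), tolerance = 1e-10)
  expect_equal(m$rmse, sqrt(mean(err^2)), tolerance = 1e-10)
  expect_equal(m$mae, mean(abs(err)), tolerance = 1e-10)
  expect_equal(m$r2, 1 - sum(err^2) / sum((res$age - mean(res$age))^2),
               tolerance = 1e-10)
  expect_true(m$r_lo <= m$r && m$r <= m$r_hi)
  expect_gte(m$rmse, m$mae)

  perfect <- tibble::tibble(age = res$age, predicted_age = res$age)
  mp <- prediction_metrics(perfect)
  expect_equal(mp$r, 1)
  expect_equal(mp$r2, 1)
  expect_equal(mp$rmse, 0)
  expect_equal(mp$mae, 0)

  flat <- tibble::tibble(age = res$age, predicted_age = rep(mean(res$age), 5))
  expect_equal(prediction_metrics(flat)$r2, 0)

  expect_error(prediction_metrics(res[1:2, ]), "at least 3")
  same_age <- tibble::tibble(age = rep(60, 5), predicted_age = 1:5)
  expect_error(prediction_metrics(same_age), "zero variance")
})

test_that("randomized search returns candidates inside the space, deterministically", {
  sim <- small_sim(n = 200, seed = 49)
  rf <- residualize_features(average_hemispheres(sim$features), sim$cohort)
  age <- sim$cohort$age

  single <- list(max_depth = 4, n_estimators = 30, learning_rate = 0.1)
  got <- tune_params(rf, age, single, n_folds = 4, n_iterations = 3,
                     seed = 50, engine = "lm")
  expect_equal(got$max_depth, 4L)
  expect_equal(got$n_estimators, 30L)

  space <- list(max_depth = c(2, 5), n_estimators = c(20, 40),
                learning_rate = c(0.1, 0.3))
  for (s in c(51, 52)) {
    p <- tune_params(rf, age, space, n_folds = 4, n_iterations = 4,
                     seed = s, engine = "lm")
    expect_true(p$max_depth %in% space$max_depth)
    expect_true(p$n_estimators %in% space$n_estimators)
    expect_true(p$learning_rate %in% space$learning_rate)
  }
  p1 <- tune_params(rf, age, space, n_folds = 4, n_iterations = 4, seed = 51,
                    engine = "lm")
  p2 <- tune_params(rf, age, space, n_folds = 4, n_iterations = 4, seed = 51,
                    engine = "lm")
  expect_identical(unclass(p1), unclass(p2))
  expect_error(tune_params(rf[1:3, ], age[1:3], space, n_folds = 10),
               "folds")
})

test_that("on clean linear data a deeper booster never scores worse in CV", {
  set.seed(53)
  n <- 300
  age <- runif(n, 45, 82)
  feats <- tibble::tibble(v1 = -20 * age + 5000, v2 = 10 * age - 200)
  scores <- sapply(c(1, 8), function(d) {
    p <- model_params(engine = "xgboost", max_depth = d, n_estimators = 40,
                      learning_rate = 0.3, n_folds = 5, seed = 53)
    res <- crossval_predict(feats, age, p,
                            folds = make_folds(n, 5, seed = 53))
    mean(abs(res$predicted_age - res$age))
  })
  expect_lte(scores[2], scores[1] + 1e-8)
})

test_that("permutation importance ranks the informative feature first and is seeded", {
  for (s in c(54, 55, 56)) {
    set.seed(s)
    n <- 500
    age <- runif(n, 45, 82)
    feats <- tibble::as_tibble(matrix(rnorm(n * 5), n,
                                      dimnames = list(NULL, paste0("noise", 1:5))))
    feats$signal <- -30 * age + rnorm(n, sd = 50)
    fit <- fit_brainage(feats, age, model_params(engine = "lm"))
    imp <- permutation_importance(fit, feats, age, n_repeats = 3, seed = s)
    expect_equal(imp$feature[1], "signal")
  }

  # ignored feature scores zero; same seed reproduces exactly
  set.seed(57)
  feats2 <- tibble::tibble(x = rnorm(100), flat = rep(1, 100))
  age2 <- 60 + feats2$x
  fit2 <- fit_brainage(feats2, age2, model_params(engine = "lm"))
  i1 <- permutation_importance(fit2, feats2, age2, n_repeats = 2, seed = 58)
  i2 <- permutation_importance(fit2, feats2, age2, n_repeats = 2, seed = 58)
  expect_identical(i1, i2)
  expect_equal(i1$importance[i1$feature == "flat"], 0)
})

test_that("reduced models on the top-4 important features stay close in accuracy", {
  sim <- small_sim(n = 1500, seed = 59)
  rf <- residualize_features(average_hemispheres(sim$features), sim$cohort)
  age <- sim$cohort$age
  members <- region_blocks()$base_region[region_blocks()$block == 3]
  full_feats <- rf[, c("participant_id", members)]
  folds <- make_folds(nrow(rf), 5, seed = 59)
  full <- crossval_predict(full_feats, age, lm_params, folds = folds)

  fit <- fit_brainage(full_feats, age, model_params(engine = "lm"))
  imp <- permutation_importance(fit, full_feats, age, n_repeats = 3,
                                seed = 59)
  top4 <- imp$feature[1:4]
  reduced <- crossval_predict(rf[, c("participant_id", top4)], age,
                              lm_params, folds = folds)
  expect_lt(abs(prediction_metrics(full)$r - prediction_metrics(reduced)$r),
            0.05)
})
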