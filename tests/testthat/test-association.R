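test_that("age-bias correction removes the age dependence exactly", {
  set.seed(61)
  n <- 50
  age <- runif(n, 45, 82)
  delta <- -0.5 * age + rnorm(n)
  corrected <- age_bias_correct(delta, age)
  expect_lt(abs(cor(corrected, age)), 1e-10)

  # matches the normal-equations oracle
  oracle <- resid_bruteforce(matrix(delta), cbind(1, age))
  expect_equal(corrected, drop(oracle), tolerance = 1e-10,
               ignore_attr = TRUE)

  # already-orthogonal input: centering only
  ortho <- drop(oracle)
  expect_equal(age_bias_correct(ortho + 5, age), ortho, tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(age_bias_correct(delta, rep(60, n)), "constant")
})

test_that("exposure regression recovers a planted effect and validates designs", {
  set.seed(62)
  n <- 10000
  age <- runif(n, 45, 82)
  births <- sample(0:5, n, replace = TRUE)
  delta <- -0.13 * births + 0.08 * (age - 60) + rnorm(n, sd = 2)
  out <- exposure_regression(delta, births, age)
  expect_lt(abs(out$beta - (-0.13)), 3 * out$se)
  expect_equal(out$t, out$beta / out$se, tolerance = 1e-10)
  expect_equal(out$n, n)

  # extended covariate set is honoured and recorded
  covs <- data.frame(bmi = rnorm(n, 27, 4), site = sample(c("a", "b"), n,
                                                          replace = TRUE))
  out2 <- exposure_regression(delta, births, age, covariates = covs)
  expect_match(out2$covariates, "bmi")
  expect_true(out2$p >= 0 && out2$p <= 1)

  dup <- data.frame(age_copy = age)
  expect_error(exposure_regression(delta, births, age, covariates = dup),
               "aliased")
})

test_that("the correlated-estimates Z test matches its closed forms", {
  a <- tibble::tibble(feature_set = "m1", beta = -0.10, se = 0.02)
  b <- tibble::tibble(feature_set = "m2", beta = -0.10, se = 0.03)
  same <- compare_associations(a, b, rho = 0.4)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  b2 <- tibble::tibble(feature_set = "m2", beta = -0.16, se = 0.02)
  zt <- compare_associations(a, b2, rho = 0)
  expect_equal(zt$z, (a$beta - b2$beta) / (0.02 * sqrt(2)),
               tolerance = 1e-12)

  # antisymmetric under swapping the pair
  expect_equal(compare_associations(b2, a, rho = 0.3)$z,
               -compare_associations(a, b2, rho = 0.3)$z)

  expect_error(compare_associations(a, b2, rho = 1.2), "inside")
  zero_se <- tibble::tibble(feature_set = "z", beta = 0, se = 0)
  expect_error(compare_associations(zero_se, zero_se, rho = 0),
               "non-positive")
})

test_that("BH adjustment reproduces published table values and the step-up rule", {
  # two-test case
  expect_equal(fdr_adjust(c(1.563e-5, 7.024e-10)),
               c(1.563e-5, 1.4048e-9), tolerance = 1e-3)

  # six regions: the min-over-larger-ranks rule binds for the rank-2 p-value
  p9 <- c(parahippocampal = .099, thalamus = .003, putamen = 1.08e-5,
          hippocampus = 8.77e-5, amygdala = 1.13e-5, accumbens = 9.90e-12)
  adj <- fdr_adjust(p9)
  expect_equal(unname(adj["putamen"]), 2.253e-5, tolerance = 0.01)
  # putamen (rank 2) is capped by amygdala's rank-3 value: 1.13e-5 * 6 / 3
  expect_equal(unname(adj["putamen"]), unname(adj["amygdala"]))
  expect_equal(unname(adj["putamen"]), 1.13e-5 * 6 / 3, tolerance = 1e-12)
  expect_equal(unname(adj["hippocampus"]), 1.315e-4, tolerance = 0.01)
  expect_equal(unname(adj["accumbens"]), 5.94e-11, tolerance = 0.01)

  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH matches a brute-force step-up on many random vectors", {
  set.seed(63)
  for (i in 1:1000) {
    m <- sample(1:12, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(fdr_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("Wilks Z reproduces the published log-likelihood arithmetic", {
  w <- wilks_z(c(10.568, 0.753))
  expect_equal(round(w$z, 3), c(4.597, 1.227))
  expect_equal(w$p, pchisq(2 * c(10.568, 0.753), 1, lower.tail = FALSE))

  zero <- wilks_z(0)
  expect_equal(zero$z, 0)
  expect_equal(zero$p, 1)
  expect_equal(wilks_z(-1e-12)$delta_ll, 0)  # tolerance clamp
  expect_error(wilks_z(-0.5), "non-negative")
})

test_that("weighted polynomial fits interpolate exact generating curves", {
  set.seed(64)
  births <- rep(0:7, times = c(40, 30, 60, 30, 15, 10, 8, 7))

  # data exactly on a line: quadratic term vanishes, comparison F ~ 0
  lin_delta <- 0.3 - 0.12 * births + rnorm(length(births), sd = 1e-9)
  f1 <- polynomial_group_fit(lin_delta, births)
  expect_lt(abs(f1$quadratic$gamma), 1e-6)
  # the linear model already interpolates the group means, so the quadratic
  # term can reduce the (numerically zero) residual no further
  expect_lt(sum(resid(f1$fit_linear)^2), 1e-12)
  expect_lt(sum(resid(f1$fit_quadratic)^2), 1e-12)
  expect_equal(f1$linear$beta, -0.12, tolerance = 1e-6)

  # data exactly on a parabola: degree-2 fit recovers both coefficients
  par_delta <- 0.5 - 0.2 * births + 0.03 * births^2 +
    rnorm(length(births), sd = 1e-9)
  f2 <- polynomial_group_fit(par_delta, births)
  expect_equal(f2$quadratic$beta, -0.2, tolerance = 1e-6)
  expect_equal(f2$quadratic$gamma, 0.03, tolerance = 1e-6)

  # raw and orthogonal parameterizations give identical fitted values
  noisy <- 0.3 - 0.1 * births + rnorm(length(births), sd = 2)
  f3 <- polynomial_group_fit(noisy, births)
  orth <- lm(mean ~ poly(exposure, 2), data = f3$groups,
             weights = 1 / f3$groups$se^2)
  expect_equal(unname(fitted(f3$fit_quadratic)), unname(fitted(orth)),
               tolerance = 1e-10)
  cmp_orth <- anova(f3$fit_linear, orth)
  expect_equal(f3$f_compare, cmp_orth$F[2], tolerance = 1e-10)
})

test_that("tail merging pools sparse parity groups at their weighted position", {
  set.seed(65)
  births <- c(rep(0, 30), rep(1, 25), rep(2, 40), rep(3, 20), rep(4, 10),
              rep(5, 6), rep(6, 3), rep(7, 2), rep(9, 1))
  delta <- rnorm(length(births))
  fit <- polynomial_group_fit(delta, births, merge_tail_at = 6)
  expect_equal(nrow(fit$groups), 7)  # 0..5 plus one merged tail group
  tail_pos <- sum(c(6, 6, 6, 7, 7, 9) * 0) + (6 * 3 + 7 * 2 + 9 * 1) / 6
  expect_equal(max(fit$groups$exposure), tail_pos)
  expect_equal(sum(fit$groups$n), length(births))

  lone <- c(rep(0, 20), rep(1, 20), rep(2, 20), rep(3, 20), 4)
  expect_error(polynomial_group_fit(rnorm(81), lone), "fewer than 2")
})

test_that("leave-one-out log-likelihoods isolate unique region contributions", {
  set.seed(66)
  n <- 1200
  r1 <- rnorm(n); r2 <- rnorm(n); r3 <- rnorm(n)  # r3 orthogonal to outcome
  births <- 1.5 + 0.4 * r1 + 0.3 * r2 + rnorm(n)
  deltas <- tibble::tibble(r1 = r1, r2 = r2, r3 = r3)
  out <- nested_ll_comparison(deltas, births)
  expect_true(all(out$delta_ll >= 0))
  expect_equal(out$z, sqrt(2 * out$delta_ll), tolerance = 1e-6)
  expect_true(all(out$p_adj >= out$p))
  expect_lt(out$delta_ll[out$region == "r3"], 2)
  expect_gt(out$delta_ll[out$region == "r1"], 10)
  expect_gt(out$p[out$region == "r3"], 0.05)

  expect_error(nested_ll_comparison(deltas[, 1, drop = FALSE], births),
               "at least 2")
})

test_that("the parous contrast is antisymmetric and recovers a planted d", {
  set.seed(67)
  # identical group distributions built from the same draws: d is exactly 0
  base <- rnorm(300)
  age0 <- runif(300, 45, 82)
  delta0 <- c(base, base)
  parous0 <- rep(c(TRUE, FALSE), each = 300)
  same <- group_contrast(delta0, parous0, c(age0, age0))
  expect_equal(same$d, 0, tolerance = 1e-12)

  # swapping labels negates beta and d
  noisy_delta <- delta0 + rnorm(600, sd = 0.3)
  sw <- group_contrast(noisy_delta, parous0, c(age0, age0))
  sw2 <- group_contrast(noisy_delta, !parous0, c(age0, age0))
  expect_equal(sw2$beta, -sw$beta, tolerance = 1e-10)
  expect_equal(sw2$d, -sw$d, tolerance = 1e-10)
  expect_equal(sign(sw$d), sign(sw$beta))

  # planted shift of 0.12 pooled-SD units at the reference split
  n1 <- 15490; n0 <- 4297
  age <- runif(n1 + n0, 45, 82)
  parous <- c(rep(TRUE, n1), rep(FALSE, n0))
  delta <- rnorm(n1 + n0) + ifelse(parous, 0.12, 0)
  got <- group_contrast(delta, parous, age)
  expect_lt(abs(got$d - 0.12), 3 * got$d_se)
  expect_equal(got$n_parous, n1)
  expect_equal(got$n_nulliparous, n0)
  expect_equal(got$d_se,
               sqrt((n1 + n0) / (n1 * n0) + got$d^2 / (2 * (n1 + n0))),
               tolerance = 1e-12)

  expect_error(group_contrast(rnorm(10), rep(TRUE, 10), runif(10, 45, 80)),
               "non-empty")
})

test_that("Frisch-Waugh: covariate-adjusted and residualized regressions agree", {
  set.seed(68)
  n <- 800
  age <- runif(n, 45, 82)
  births <- pmax(0, round(2 + 0.02 * (60 - age) + rnorm(n)))
  delta <- -0.1 * births + 0.05 * age + rnorm(n, sd = 2)

  direct <- exposure_regression(delta, births, age)
  d_res <- age_bias_correct(delta, age)
  b_res <- age_bias_correct(births, age)
  via_resid <- coef(lm(d_res ~ b_res))[["b_res"]]
  expect_equal(direct$beta, via_resid, tolerance = 1e-8)
})

test_that("pairwise comparisons use delta correlations and adjust p-values", {
  set.seed(69)
  n <- 500
  age <- runif(n, 45, 82)
  births <- sample(0:4, n, replace = TRUE)
  shared <- rnorm(n)
  d1 <- -0.2 * births + shared + rnorm(n)
  d2 <- shared + rnorm(n)
  d3 <- rnorm(n)
  assocs <- dplyr::bind_rows(
    exposure_regression(d1, births, age, feature_set = "s1"),
    exposure_regression(d2, births, age, feature_set = "s2"),
    exposure_regression(d3, births, age, feature_set = "s3")
  )
  deltas <- tibble::tibble(s1 = age_bias_correct(d1, age),
                           s2 = age_bias_correct(d2, age),
                           s3 = age_bias_correct(d3, age))
  cmp <- pairwise_comparisons(assocs, deltas)
  expect_equal(nrow(cmp), 3)
  r12 <- cmp[cmp$set_1 == "s1" & cmp$set_2 == "s2", ]
  expect_equal(r12$rho, cor(deltas$s1, deltas$s2))
  expect_equal(cmp$p_adj, fdr_adjust(cmp$p))
})
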