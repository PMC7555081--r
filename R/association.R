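#' Age-bias correction of brain-age deltas
#'
#' Brain-age predictions regress toward the training mean, leaving a
#' systematic age dependence in the delta. This removes it by ordinary
#' least squares: the returned values are the residuals of
#' `delta ~ 1 + age` and are exactly uncorrelated with age.
#'
#' @param delta Brain-age deltas (years).
#' @param age Chronological ages (years), same length.
#' @return Numeric vector of corrected deltas.
#' @export
age_bias_correct <- function(delta, age) {
  stopifnot(length(delta) == length(age))
  if (sd(age) == 0) abort("age is constant; bias correction is undefined.")
  resid(lm(delta ~ age))
}

# Shared design-building + OLS with rank checks; returns the lm fit.
checked_lm <- function(df, formula) {
  fit <- lm(formula, data = df)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("rank-deficient design; aliased terms: ",
                 paste(bad, collapse = ", ")))
  }
  if (nrow(df) <= length(coef(fit))) {
    abort("fewer observations than parameters.")
  }
  fit
}

#' Association between brain-age delta and an exposure count
#'
#' OLS regression of delta on the exposure (number of childbirths) with
#' chronological age — and, optionally, further covariates — adjusted for.
#' Classical (non-robust) standard errors and a two-sided t-test on the
#' exposure coefficient.
#'
#' @param delta Brain-age deltas (years).
#' @param exposure Exposure counts (births).
#' @param age Chronological ages; always included as a covariate.
#' @param covariates Optional data frame of additional covariates
#'   (character columns are treated as categorical).
#' @param feature_set Label recorded with the result.
#' @return A one-row tibble of class `"delta_association"`: `feature_set`,
#'   `beta`, `se`, `t`, `p`, `n`, `covariates`.
#' @export
exposure_regression <- function(delta, exposure, age, covariates = NULL,
                                feature_set = "delta") {
  df <- data.frame(.delta = delta, .exposure = exposure, .age = age)
  covnames <- "age"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (v in names(covariates)) {
      if (is.character(covariates[[v]])) {
        covariates[[v]] <- factor(covariates[[v]])
      }
    }
    covnames <- c(covnames, names(covariates))
    df <- cbind(df, covariates)
  }
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  fit <- checked_lm(df, .delta ~ .)
  sm <- summary(fit)$coefficients
  structure(
    tibble(
      feature_set = feature_set,
      beta = sm[".exposure", "Estimate"],
      se = sm[".exposure", "Std. Error"],
      t = sm[".exposure", "t value"],
      p = sm[".exposure", "Pr(>|t|)"],
      n = nrow(df),
      covariates = paste(covnames, collapse = "+")
    ),
    class = c("delta_association", "tbl_df", "tbl", "data.frame")
  )
}

#' Z test for the difference between two correlated coefficients
#'
#' Compares the exposure coefficients of two models fitted on the same
#' participants:
#' \deqn{Z = (\beta_1 - \beta_2) / \sqrt{\sigma_1^2 + \sigma_2^2 -
#'   2\rho\sigma_1\sigma_2}}
#' where \eqn{\rho} captures the dependence between the two estimates. The
#' package operationalizes \eqn{\rho} as the Pearson correlation between
#' the two age-corrected delta vectors (see [pairwise_comparisons()]), but
#' any externally supplied value can be used. The p-value is two-sided
#' standard normal.
#'
#' @param a,b One-row association results (or lists with `beta` and `se`).
#' @param rho Correlation inducing dependence between the estimates, in
#'   (-1, 1).
#' @return One-row tibble: `set_1`, `set_2`, `rho`, `z`, `p`.
#' @export
compare_associations <- function(a, b, rho) {
  if (abs(rho) >= 1) abort("`rho` must lie strictly inside (-1, 1).")
  v <- a$se^2 + b$se^2 - 2 * rho * a$se * b$se
  if (!is.finite(v) || v <= 0) {
    abort("non-positive variance under the radical.")
  }
  z <- (a$beta - b$beta) / sqrt(v)
  tibble(
    set_1 = if (!is.null(a$feature_set)) a$feature_set else "a",
    set_2 = if (!is.null(b$feature_set)) b$feature_set else "b",
    rho = rho, z = z, p = 2 * pnorm(-abs(z))
  )
}

#' All pairwise coefficient comparisons across feature sets
#'
#' Runs [compare_associations()] for every pair of feature sets, taking
#' \eqn{\rho} for each pair as the Pearson correlation between the two
#' age-corrected delta vectors, and adjusts the two-sided p-values across
#' pairs by Benjamini-Hochberg.
#'
#' @param assocs Tibble of association rows (one per feature set), e.g.
#'   stacked [exposure_regression()] results.
#' @param deltas Tibble (or named list) of age-corrected delta vectors,
#'   one column per feature set, aligned across participants.
#' @return Tibble with one row per unordered pair: `set_1`, `set_2`,
#'   `rho`, `z`, `p`, `p_adj`.
#' @export
pairwise_comparisons <- function(assocs, deltas) {
  deltas <- as_tibble(deltas)
  sets <- assocs$feature_set
  stopifnot(all(sets %in% names(deltas)))
  pairs <- utils::combn(seq_along(sets), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    i1 <- pairs[1, i]; i2 <- pairs[2, i]
    rho <- cor(deltas[[sets[i1]]], deltas[[sets[i2]]])
    compare_associations(assocs[i1, ], assocs[i2, ], rho)
  })
  out$p_adj <- fdr_adjust(out$p)
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: `p_adj(i)` is the minimum over all
#' larger-or-equal ranks `j` of `p(j) * m / rank(j)`, capped at 1. A thin
#' wrapper over [stats::p.adjust()] with input validation, kept as a named
#' stage of the pipeline.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Wilks Z from a log-likelihood difference
#'
#' Under Wilks' theorem, twice the log-likelihood difference between
#' nested models differing by one parameter is asymptotically
#' \eqn{\chi^2(1)}; the signed root `sqrt(2 * delta_ll)` is reported as Z.
#'
#' @param delta_ll Non-negative log-likelihood difference(s); values
#'   negative within numerical tolerance are clamped to zero.
#' @return Tibble `delta_ll`, `z`, `p` (upper \eqn{\chi^2(1)} tail of
#'   `2 * delta_ll`).
#' @export
wilks_z <- function(delta_ll) {
  if (any(delta_ll < -1e-8)) {
    abort("`delta_ll` must be non-negative (full model cannot fit worse).")
  }
  dll <- pmax(delta_ll, 0)
  tibble(delta_ll = dll, z = sqrt(2 * dll),
         p = pchisq(2 * dll, df = 1, lower.tail = FALSE))
}

#' Leave-one-out log-likelihood comparison across regions
#'
#' Fits a Gaussian multiple regression of the exposure on all
#' region-specific brain-age deltas (plus age, if supplied), then drops one
#' region at a time and compares log-likelihoods. For each region
#' \eqn{\Delta LL = LL_{full} - LL_{reduced} \ge 0}, significance is the
#' upper \eqn{\chi^2(1)} tail of \eqn{2\Delta LL} (one parameter left out),
#' and p-values are BH-adjusted across regions. A region whose delta adds
#' no unique information beyond the others scores \eqn{\Delta LL \approx 0}.
#'
#' @param region_deltas Tibble of delta vectors, one column per region
#'   (`participant_id` ignored).
#' @param exposure Exposure counts.
#' @param age Optional ages, included in both full and reduced models.
#' @return A `"nested_comparison"` tibble: `region`, `delta_ll`, `z`, `p`,
#'   `p_adj`.
#' @export
nested_ll_comparison <- function(region_deltas, exposure, age = NULL) {
  regions <- setdiff(names(region_deltas), "participant_id")
  if (length(regions) < 2) abort("need at least 2 regions.")
  df <- as.data.frame(region_deltas[, regions])
  df$.exposure <- exposure
  if (!is.null(age)) df$.age <- age
  full <- checked_lm(df, .exposure ~ .)
  ll_full <- as.numeric(logLik(full))
  out <- purrr::map_dfr(regions, function(rg) {
    reduced <- lm(.exposure ~ ., data = df[, setdiff(names(df), rg)])
    tibble(region = rg, delta_ll = ll_full - as.numeric(logLik(reduced)))
  })
  w <- wilks_z(out$delta_ll)
  out$delta_ll <- w$delta_ll
  out$z <- w$z
  out$p <- w$p
  out$p_adj <- fdr_adjust(out$p)
  structure(out, class = c("nested_comparison", class(tibble())))
}

#' Weighted polynomial fits of delta on exposure group means
#'
#' Participants are grouped by exposure count, tail groups at or above
#' `merge_tail_at` births are merged (placed at their count-weighted mean
#' exposure) to stabilize the group means, and degree-1 and degree-2
#' polynomials are fitted to the group means by weighted least squares
#' with weights \eqn{1/SE^2} (SE = within-group SD/\eqn{\sqrt{n}}).
#' Reports both fits, the overall F of each, the F comparing them, and the
#' degree-2 fit reparameterized in orthogonal polynomials (identical
#' fitted values; a collinearity cross-check).
#'
#' Deltas should be age-bias corrected (see [age_bias_correct()]) before
#' grouping.
#'
#' @param delta Corrected brain-age deltas.
#' @param exposure Exposure counts.
#' @param merge_tail_at Groups with exposure at or above this count are
#'   pooled.
#' @return A `"parity_polyfit"` list: `groups` (tibble `exposure`, `n`,
#'   `mean`, `se`), `linear` and `quadratic` coefficient tibbles,
#'   `orthogonal` coefficients, `f_linear`, `f_quadratic`, `f_compare`,
#'   `p_compare`, and the two `lm` fits.
#' @export
polynomial_group_fit <- function(delta, exposure, merge_tail_at = 6) {
  keep <- complete.cases(delta, exposure)
  delta <- delta[keep]
  exposure <- exposure[keep]
  gid <- ifelse(exposure >= merge_tail_at, merge_tail_at, exposure)
  groups <- tibble(delta = delta, gid = gid, exposure = exposure) %>%
    group_by(.data$gid) %>%
    summarise(
      exposure = sum(.data$exposure) / n(),  # count-weighted mean position
      n = n(),
      mean = mean(.data$delta),
      se = sd(.data$delta) / sqrt(n()),
      .groups = "drop"
    ) %>%
    select("exposure", "n", "mean", "se") %>%
    arrange(.data$exposure)
  if (any(groups$n < 2)) {
    abort("a group has fewer than 2 members; its SE is undefined.")
  }
  if (nrow(groups) < 4) {
    abort("need at least 4 distinct exposure groups after merging.")
  }
  w <- 1 / groups$se^2
  lin <- lm(mean ~ exposure, data = groups, weights = w)
  quad <- lm(mean ~ exposure + I(exposure^2), data = groups, weights = w)
  orth <- lm(mean ~ poly(exposure, 2), data = groups, weights = w)
  fstat <- function(fit) {
    fs <- summary(fit)$fstatistic
    tibble(f = unname(fs[1]),
           p = pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  }
  cmp <- anova(lin, quad)
  sm_l <- summary(lin)$coefficients
  sm_q <- summary(quad)$coefficients
  sm_o <- summary(orth)$coefficients
  structure(
    list(
      groups = groups,
      linear = tibble(beta = sm_l["exposure", 1], se = sm_l["exposure", 2]),
      quadratic = tibble(beta = sm_q["exposure", 1],
                         beta_se = sm_q["exposure", 2],
                         gamma = sm_q["I(exposure^2)", 1],
                         gamma_se = sm_q["I(exposure^2)", 2]),
      orthogonal = tibble(beta = sm_o[2, 1], beta_se = sm_o[2, 2],
                          gamma = sm_o[3, 1], gamma_se = sm_o[3, 2]),
      f_linear = fstat(lin), f_quadratic = fstat(quad),
      f_compare = cmp$F[2], p_compare = cmp$`Pr(>F)`[2],
      fit_linear = lin, fit_quadratic = quad
    ),
    class = "parity_polyfit"
  )
}

#' @importFrom stats pf
#' @export
print.parity_polyfit <- function(x, ...) {
  cat("Weighted polynomial group fit (", nrow(x$groups), "groups )\n")
  cat(sprintf("  linear:    beta = %.4f +/- %.4f  (F = %.2f, p = %.3g)\n",
              x$linear$beta, x$linear$se, x$f_linear$f, x$f_linear$p))
  cat(sprintf("  quadratic: beta = %.4f +/- %.4f, gamma = %.4f +/- %.4f\n",
              x$quadratic$beta, x$quadratic$beta_se, x$quadratic$gamma,
              x$quadratic$gamma_se))
  cat(sprintf("  linear vs quadratic: F = %.3f, p = %.3g\n",
              x$f_compare, x$p_compare))
  invisible(x)
}

#' Parous versus nulliparous group contrast
#'
#' OLS of delta on a parity indicator with age as covariate, plus Cohen's d
#' computed on age-corrected deltas (pooled-SD standardized mean
#' difference, parous minus nulliparous, so d carries the sign of beta)
#' with the large-sample standard error
#' \eqn{\sqrt{(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))}}.
#'
#' @param delta Brain-age deltas.
#' @param parous Logical (or 0/1) group indicator; `TRUE` = parous.
#' @param age Chronological ages.
#' @return One-row tibble: `beta`, `se`, `t`, `p`, `d`, `d_se`,
#'   `n_parous`, `n_nulliparous`.
#' @export
group_contrast <- function(delta, parous, age) {
  parous <- as.logical(parous)
  keep <- complete.cases(delta, parous, age)
  delta <- delta[keep]; parous <- parous[keep]; age <- age[keep]
  n1 <- sum(parous); n0 <- sum(!parous)
  if (n1 == 0 || n0 == 0) abort("both groups must be non-empty.")
  fit <- checked_lm(data.frame(.delta = delta, .parous = as.numeric(parous),
                               .age = age), .delta ~ .)
  sm <- summary(fit)$coefficients
  corrected <- age_bias_correct(delta, age)
  sp <- sqrt(((n1 - 1) * var(corrected[parous]) +
                (n0 - 1) * var(corrected[!parous])) / (n1 + n0 - 2))
  d <- (mean(corrected[parous]) - mean(corrected[!parous])) / sp
  d_se <- sqrt((n1 + n0) / (n1 * n0) + d^2 / (2 * (n1 + n0)))
  tibble(beta = sm[".parous", 1], se = sm[".parous", 2],
         t = sm[".parous", 3], p = sm[".parous", 4],
         d = d, d_se = d_se, n_parous = n1, n_nulliparous = n0)
}
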