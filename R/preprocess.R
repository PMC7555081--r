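#' Apply participant-level exclusion rules
#'
#' Reproduces the cohort-definition stage of the analysis: participants are
#' removed when (1) they carry a pre-existing diagnosis exclusion flag,
#' (2) their surface-quality score, mean cortical volume, or mean
#' subcortical volume lies more than `sd_threshold` SDs from the sample mean
#' (strict inequality: a point at exactly the threshold is retained), or
#' (3) their exposure (number of childbirths) is missing. Z-scores are
#' computed on the sample remaining after the diagnosis exclusion but before
#' any metric exclusion, and the retained set is the complement of the union
#' of all flags, so the evaluation order of the metric rules is immaterial.
#' A metric with zero spread flags nobody (no point deviates from the mean).
#'
#' @param cohort Cohort tibble (see [simulate_cohort()]); must contain
#'   `participant_id`, `n_childbirths`, `diagnosis_excluded`, `qc_score_lh`,
#'   `qc_score_rh`.
#' @param features Feature tibble with `participant_id` and regional volume
#'   columns; cortical/subcortical membership is taken from [dk_regions()]
#'   for the columns present.
#' @param sd_threshold Outlier threshold in SD units (default 4).
#' @param qc_combine How to combine the two per-hemisphere quality scores
#'   before thresholding: `"average"` (default) or `"worst"` (minimum, i.e.
#'   most negative Euler proxy).
#' @return A list with the filtered `cohort` and `features` and a `report`
#'   of class `"qc_report"`: per-flag counts, the flag table itself
#'   (joinable by `participant_id`), and retained/total n.
#' @export
exclude_participants <- function(cohort, features, sd_threshold = 4,
                                 qc_combine = c("average", "worst")) {
  qc_combine <- match.arg(qc_combine)
  stopifnot(nrow(cohort) == nrow(features),
            all(cohort$participant_id == features$participant_id))

  diagnosis <- as.logical(cohort$diagnosis_excluded)
  keep0 <- !diagnosis  # z-scores computed after diagnosis exclusion

  qc <- if (qc_combine == "average") {
    (cohort$qc_score_lh + cohort$qc_score_rh) / 2
  } else {
    pmin(cohort$qc_score_lh, cohort$qc_score_rh)
  }
  meta <- dk_regions()
  fcols <- setdiff(names(features), "participant_id")
  ctx <- meta$region[meta$compartment == "cortical"]
  sctx <- meta$region[meta$compartment == "subcortical"]
  ctx <- intersect(fcols, ctx)
  sctx <- intersect(fcols, sctx)
  if (length(ctx) == 0 || length(sctx) == 0) {
    abort("feature table must contain cortical and subcortical columns.")
  }
  gm_ctx <- rowMeans(features[, ctx])
  gm_sctx <- rowMeans(features[, sctx])

  zflag <- function(x, label) {
    mu <- mean(x[keep0])
    s <- sd(x[keep0])
    if (!is.finite(s)) {
      abort(paste0("metric `", label, "` is not computable."))
    }
    if (s == 0) return(rep(FALSE, length(x)))  # no spread: nothing deviates
    abs((x - mu) / s) > sd_threshold & keep0
  }
  flags <- tibble(
    participant_id = cohort$participant_id,
    diagnosis = diagnosis,
    qc_outlier = zflag(qc, "qc_score"),
    cortical_gm_outlier = zflag(gm_ctx, "mean cortical volume"),
    subcortical_gm_outlier = zflag(gm_sctx, "mean subcortical volume"),
    missing_exposure = is.na(cohort$n_childbirths)
  )
  any_flag <- flags$diagnosis | flags$qc_outlier | flags$cortical_gm_outlier |
    flags$subcortical_gm_outlier | flags$missing_exposure

  counts <- tibble(
    flag = c("diagnosis", "qc_outlier", "cortical_gm_outlier",
             "subcortical_gm_outlier", "missing_exposure", "any"),
    n = c(sum(flags$diagnosis), sum(flags$qc_outlier),
          sum(flags$cortical_gm_outlier), sum(flags$subcortical_gm_outlier),
          sum(flags$missing_exposure), sum(any_flag))
  )
  report <- structure(
    list(counts = counts, flags = flags, total_n = nrow(cohort),
         retained_n = sum(!any_flag), sd_threshold = sd_threshold),
    class = "qc_report"
  )
  list(cohort = cohort[!any_flag, ], features = features[!any_flag, ],
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Participant exclusion report\n")
  cat("  total:", x$total_n, " retained:", x$retained_n,
      " (|z| >", x$sd_threshold, "on pre-exclusion sample)\n")
  print(x$counts)
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report A `"qc_report"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(
    list(total_n = report$total_n, retained_n = report$retained_n,
         sd_threshold = report$sd_threshold,
         counts = as.data.frame(report$counts)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Average left and right hemisphere measures
#'
#' Collapses the lateralized volume table to one column per bilateral
#' region by arithmetic mean of the `lh_`/`rh_` pair; midline columns
#' (no prefix) pass through unchanged.
#'
#' @param features Feature tibble with `participant_id` and lateralized
#'   columns named `lh_<region>` / `rh_<region>`.
#' @return Tibble with `participant_id` and de-lateralized region columns.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n = 20, seed = 1))
#' ncol(average_hemispheres(sim$features))  # 43 regions + id
average_hemispheres <- function(features) {
  fcols <- setdiff(names(features), "participant_id")
  lat <- grepl("^(lh|rh)_", fcols)
  base <- unique(sub("^(lh|rh)_", "", fcols[lat]))
  out <- list()
  for (b in base) {
    l <- paste0("lh_", b)
    r <- paste0("rh_", b)
    if (!(l %in% fcols) || !(r %in% fcols)) {
      abort(paste0("unpaired lateral region: `", b, "`."))
    }
    out[[b]] <- (features[[l]] + features[[r]]) / 2
  }
  for (m in fcols[!lat]) out[[m]] <- features[[m]]
  bind_cols(tibble(participant_id = features$participant_id), as_tibble(out))
}

# Build a full-rank nuisance design matrix from cohort columns. Shorthands:
# "qc" = mean of the two hemisphere quality scores; categorical columns are
# one-hot encoded with the first level dropped.
nuisance_design <- function(cohort, nuisance) {
  if (length(nuisance) == 0) {
    return(matrix(1, nrow(cohort), 1, dimnames = list(NULL, "(Intercept)")))
  }
  cols <- list()
  for (v in nuisance) {
    if (v == "qc") {
      cols[["qc"]] <- (cohort$qc_score_lh + cohort$qc_score_rh) / 2
    } else if (!v %in% names(cohort)) {
      abort(paste0("nuisance variable `", v, "` not found in cohort."))
    } else {
      cols[[v]] <- cohort[[v]]
    }
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  for (v in names(df)) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  X <- model.matrix(~., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("nuisance design is rank deficient; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  X
}

#' Residualize features on nuisance variables
#'
#' Replaces each feature column by the residual of an ordinary
#' least-squares fit on an intercept plus the nuisance design (scanner
#' site, data quality, intracranial volume, ethnic background by default).
#' The fit uses the full supplied sample, as in the emulated study design
#' where residualization precedes any train/test split; residual columns
#' are exactly orthogonal to every nuisance regressor.
#'
#' @param features Feature tibble (`participant_id` + numeric columns).
#' @param cohort Cohort tibble aligned with `features`.
#' @param nuisance Character vector of cohort columns (or the shorthand
#'   `"qc"` for the averaged hemisphere quality score).
#' @return Tibble of residualized features, same shape as the input.
#' @export
residualize_features <- function(features, cohort,
                                 nuisance = c("site", "qc", "icv",
                                              "ethnicity")) {
  stopifnot(nrow(cohort) == nrow(features),
            all(cohort$participant_id == features$participant_id))
  X <- nuisance_design(cohort, nuisance)
  Y <- as.matrix(features[, setdiff(names(features), "participant_id")])
  qrX <- qr(X)
  R <- qr.resid(qrX, Y)
  bind_cols(tibble(participant_id = features$participant_id), as_tibble(R))
}
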