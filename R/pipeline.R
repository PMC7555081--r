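#' Pipeline run configuration
#'
#' Bundles every setting of the end-to-end analysis. Exactly one input
#' source must be given: a [sim_config()] (synthetic cohort) or
#' cohort/feature tables (in memory, or CSV paths).
#'
#' @param sim A [sim_config()], or `NULL`.
#' @param cohort,features In-memory tables, or `NULL`.
#' @param cohort_file,features_file CSV paths, or `NULL`.
#' @param k_top,k_sub Cluster counts for the top-level clustering and the
#'   subclustering of the strongest cluster.
#' @param linkage Linkage rule, see [hierarchical_clusters()].
#' @param params [model_params()] for every brain-age model of the run.
#' @param covariates Character vector of extra covariate columns for the
#'   association models (age is always included).
#' @param nuisance Residualization variables, see [residualize_features()].
#' @param sd_threshold Exclusion threshold, see [exclude_participants()].
#' @param fdr_q FDR level used when flagging significant rows.
#' @param include_global Also fit a global (all-region) brain-age model.
#' @param seed Seed for fold assignment (the simulation seed lives in
#'   `sim`).
#' @param out_dir If non-`NULL`, results are written there as CSV/JSON.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = NULL, cohort = NULL, features = NULL,
                            cohort_file = NULL, features_file = NULL,
                            k_top = 5, k_sub = 2, linkage = "average",
                            params = model_params(), covariates = NULL,
                            nuisance = c("site", "qc", "icv", "ethnicity"),
                            sd_threshold = 4, fdr_q = 0.05,
                            include_global = TRUE, seed = 42,
                            out_dir = NULL) {
  from_tables <- !is.null(cohort) && !is.null(features)
  from_files <- !is.null(cohort_file) && !is.null(features_file)
  if (sum(c(!is.null(sim), from_tables, from_files)) != 1) {
    abort(paste0("provide exactly one input source: `sim`, ",
                 "`cohort`+`features`, or `cohort_file`+`features_file`."))
  }
  structure(
    list(sim = sim, cohort = cohort, features = features,
         cohort_file = cohort_file, features_file = features_file,
         k_top = k_top, k_sub = k_sub, linkage = linkage, params = params,
         covariates = covariates, nuisance = nuisance,
         sd_threshold = sd_threshold, fdr_q = fdr_q,
         include_global = include_global, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

read_input_table <- function(path, what) {
  if (!file.exists(path)) {
    abort(paste0("missing ", what, " file: `", path, "`."))
  }
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

run_feature_set <- function(features, cols, age, params, folds, label) {
  crossval_predict(features[, c("participant_id", cols)], age, params,
                   folds = folds, feature_set = label)
}

#' Run the full regional brain-age analysis
#'
#' Executes, on one cohort: exclusions, hemisphere averaging,
#' residualization, covariance clustering of the regions, per-cluster
#' cross-validated brain-age models (shared folds, so cluster deltas are
#' comparable), exposure regressions with BH-FDR, pairwise
#' correlated-estimates Z tests, subclustering of the strongest cluster
#' with the same association battery, a parous/nulliparous contrast on the
#' strongest subcluster, single-region brain-age models for its member
#' regions, and the leave-one-out log-likelihood comparison across those
#' regions. "Strongest" always means smallest uncorrected association
#' p-value.
#'
#' @param config A [pipeline_config()].
#' @return A `"parity_pipeline"` list; see the individual elements'
#'   documentation in the methods vignette. If `config$out_dir` is set the
#'   result tables are also written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ",
                   conditionMessage(e)))
    })
  }

  if (!is.null(config$sim)) {
    sim <- stage("simulate", simulate_cohort(config$sim))
    cohort <- sim$cohort; features <- sim$features
  } else if (!is.null(config$cohort_file)) {
    cohort <- stage("read", read_input_table(config$cohort_file, "cohort"))
    features <- stage("read",
                      read_input_table(config$features_file, "features"))
  } else {
    cohort <- as_tibble(config$cohort)
    features <- as_tibble(config$features)
  }

  qc <- stage("exclude",
              exclude_participants(cohort, features, config$sd_threshold))
  cohort <- qc$cohort; features <- qc$features

  avg <- stage("average_hemispheres", average_hemispheres(features))
  resid_feats <- stage("residualize",
                       residualize_features(avg, cohort, config$nuisance))

  clustering <- stage("cluster", hierarchical_clusters(
    spearman_matrix(resid_feats), k = config$k_top, linkage = config$linkage
  ))
  sets <- cluster_feature_sets(clustering)
  if (config$include_global) {
    sets <- c(list(global = setdiff(names(resid_feats), "participant_id")),
              sets)
  }

  n <- nrow(cohort)
  folds <- make_folds(n, config$params$n_folds, config$seed)
  age <- cohort$age
  exposure <- cohort$n_childbirths
  covs <- if (!is.null(config$covariates)) {
    cohort[, config$covariates, drop = FALSE]
  } else {
    NULL
  }

  results <- stage("brainage", purrr::map(
    names(sets),
    function(lb) run_feature_set(resid_feats, sets[[lb]], age,
                                 config$params, folds, lb)
  ) %>% setNames(names(sets)))
  metrics <- purrr::map_dfr(results, prediction_metrics)
  corrected <- purrr::map(results, ~age_bias_correct(.x$delta, .x$age)) %>%
    as_tibble()

  cluster_labels <- setdiff(names(sets), "global")
  assoc <- stage("associate", purrr::map_dfr(
    names(sets),
    function(lb) exposure_regression(results[[lb]]$delta, exposure, age,
                                     covariates = covs, feature_set = lb)
  ))
  cl_assoc <- assoc[assoc$feature_set %in% cluster_labels, ]
  cl_assoc$p_adj <- fdr_adjust(cl_assoc$p)
  cl_assoc$significant <- cl_assoc$p_adj < config$fdr_q
  comparisons <- stage("compare", pairwise_comparisons(
    cl_assoc, corrected[, cluster_labels]
  ))

  strongest <- cl_assoc$feature_set[which.min(cl_assoc$p)]
  strongest_id <- as.integer(sub("cluster_", "", strongest))

  subclustering <- stage("subcluster", subcluster(
    resid_feats, clustering, strongest_id, k = config$k_sub,
    linkage = config$linkage
  ))
  subsets <- cluster_feature_sets(subclustering) %>%
    setNames(paste0("sub", names(.)))
  sub_results <- stage("brainage_sub", purrr::map(
    names(subsets),
    function(lb) run_feature_set(resid_feats, subsets[[lb]], age,
                                 config$params, folds, lb)
  ) %>% setNames(names(subsets)))
  sub_metrics <- purrr::map_dfr(sub_results, prediction_metrics)
  sub_corrected <- purrr::map(sub_results,
                              ~age_bias_correct(.x$delta, .x$age)) %>%
    as_tibble()
  sub_assoc <- purrr::map_dfr(
    names(subsets),
    function(lb) exposure_regression(sub_results[[lb]]$delta, exposure, age,
                                     covariates = covs, feature_set = lb)
  )
  sub_assoc$p_adj <- fdr_adjust(sub_assoc$p)
  sub_comparisons <- pairwise_comparisons(sub_assoc, sub_corrected)

  strongest_sub <- sub_assoc$feature_set[which.min(sub_assoc$p)]
  contrast <- stage("contrast", group_contrast(
    sub_results[[strongest_sub]]$delta, cohort$parous, age
  ))

  region_names <- subsets[[strongest_sub]]
  region_results <- stage("brainage_regions", purrr::map(
    region_names,
    function(rg) run_feature_set(resid_feats, rg, age, config$params,
                                 folds, rg)
  ) %>% setNames(region_names))
  region_assoc <- purrr::map_dfr(region_names, function(rg) {
    res <- region_results[[rg]]
    bind_cols(tibble(r_age = cor(res$predicted_age, res$age)),
              exposure_regression(res$delta, exposure, age,
                                  covariates = covs, feature_set = rg))
  }) %>% rename(region = "feature_set") %>%
    select("region", "r_age", "beta", "se", "t", "p", "n", "covariates")
  region_assoc$p_adj <- fdr_adjust(region_assoc$p)

  region_deltas <- purrr::map(region_results, "delta") %>% as_tibble()
  nested <- stage("nested_ll",
                  nested_ll_comparison(region_deltas, exposure, age))

  out <- structure(
    list(
      qc_report = qc$report, clustering = clustering,
      subclustering = subclustering,
      metrics = bind_rows(metrics, sub_metrics),
      brainage = c(results, sub_results, region_results),
      corrected_deltas = bind_cols(
        tibble(participant_id = cohort$participant_id), corrected,
        sub_corrected
      ),
      associations = cl_assoc, comparisons = comparisons,
      sub_associations = sub_assoc, sub_comparisons = sub_comparisons,
      strongest_cluster = strongest, strongest_subcluster = strongest_sub,
      contrast = contrast, region_associations = region_assoc,
      nested = nested,
      global_association = if (config$include_global) {
        assoc[assoc$feature_set == "global", ]
      } else {
        NULL
      },
      provenance = list(
        seed = config$seed,
        sim_seed = if (!is.null(config$sim)) config$sim$seed else NULL,
        engine = config$params$engine, params = unclass(config$params),
        k_top = config$k_top, k_sub = config$k_sub,
        linkage = config$linkage, nuisance = config$nuisance,
        sd_threshold = config$sd_threshold, fdr_q = config$fdr_q,
        package_version = as.character(utils::packageVersion("regionage")),
        r_version = R.version.string
      )
    ),
    class = "parity_pipeline"
  )
  if (!is.null(config$out_dir)) write_results(out, config$out_dir)
  out
}

#' @export
print.parity_pipeline <- function(x, ...) {
  cat("Regional brain-age pipeline\n")
  cat("  retained n:", x$qc_report$retained_n, "of", x$qc_report$total_n,
      "\n")
  cat("  clusters:", x$clustering$k,
      "| strongest association:", x$strongest_cluster,
      "-> subclusters:", x$subclustering$k,
      "| strongest:", x$strongest_subcluster, "\n")
  cat("\nCluster associations (delta ~ births + age):\n")
  print(as.data.frame(x$associations[, c("feature_set", "beta", "se", "t",
                                         "p", "p_adj")]))
  invisible(x)
}

#' Write pipeline results to disk
#'
#' Emits the result tables as CSV (cluster/subcluster/region associations,
#' pairwise Z tests, nested log-likelihood comparison, cluster
#' assignments, per-model accuracy metrics) plus the QC report and a
#' provenance record (seeds, settings, versions) as JSON.
#'
#' @param x A `"parity_pipeline"`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_results <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, f) {
    utils::write.csv(as.data.frame(df), file.path(dir, f), row.names = FALSE)
  }
  wcsv(x$associations, "cluster_associations.csv")
  wcsv(x$comparisons, "cluster_pairwise_z.csv")
  wcsv(x$sub_associations, "subcluster_associations.csv")
  wcsv(x$sub_comparisons, "subcluster_pairwise_z.csv")
  wcsv(x$region_associations, "region_associations.csv")
  wcsv(x$nested, "nested_ll_comparison.csv")
  wcsv(x$metrics, "prediction_metrics.csv")
  wcsv(x$contrast, "parous_contrast.csv")
  write_clustering(x$clustering, dir, "clusters")
  write_clustering(x$subclustering, dir, "subclusters")
  write_qc_report(x$qc_report, file.path(dir, "qc_report.json"))
  jsonlite::write_json(x$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Train/test replication of the global brain-age association
#'
#' Mirrors a replication design: the global brain-age model is fitted on
#' the training participants only and applied to the held-out test
#' participants; the exposure association (delta ~ births + age), the
#' weighted polynomial group fits on age-corrected deltas, and the
#' per-parity group counts are then computed on the test sample alone.
#' Hemisphere averaging and residualization run on the combined sample, as
#' in the emulated study design.
#'
#' @param cohort,features Input tables (post-exclusion).
#' @param train_ids,test_ids Disjoint participant id sets.
#' @param params [model_params()].
#' @param nuisance Residualization variables.
#' @param merge_tail_at Tail-merge rule for [polynomial_group_fit()].
#' @return List: `metrics` (test-set accuracy), `association`, `polyfit`,
#'   `group_counts`, `n_train`, `n_test`.
#' @export
replicate_split <- function(cohort, features, train_ids, test_ids,
                            params = model_params(),
                            nuisance = c("site", "qc", "icv", "ethnicity"),
                            merge_tail_at = 6) {
  if (length(intersect(train_ids, test_ids)) > 0) {
    abort("train and test ids overlap.")
  }
  if (length(test_ids) == 0) abort("empty test set.")
  if (!all(c(train_ids, test_ids) %in% cohort$participant_id)) {
    abort("some ids are absent from the cohort.")
  }
  avg <- average_hemispheres(features)
  resid_feats <- residualize_features(avg, cohort, nuisance)
  idx_train <- match(train_ids, cohort$participant_id)
  idx_test <- match(test_ids, cohort$participant_id)

  pred <- fit_then_predict(resid_feats[idx_train, ],
                           cohort$age[idx_train],
                           resid_feats[idx_test, ], params)
  test <- tibble(
    participant_id = cohort$participant_id[idx_test],
    age = cohort$age[idx_test],
    predicted_age = pred,
    delta = pred - cohort$age[idx_test],
    feature_set = "global_test"
  )
  exposure <- cohort$n_childbirths[idx_test]
  assoc <- exposure_regression(test$delta, exposure, test$age,
                               feature_set = "global_test")
  corrected <- age_bias_correct(test$delta, test$age)
  polyfit <- polynomial_group_fit(corrected, exposure,
                                  merge_tail_at = merge_tail_at)
  group_counts <- tibble(n_childbirths = exposure) %>%
    filter(!is.na(.data$n_childbirths)) %>%
    group_by(.data$n_childbirths) %>%
    summarise(n = n(), .groups = "drop")
  list(metrics = prediction_metrics(test), association = assoc,
       polyfit = polyfit, group_counts = group_counts,
       n_train = length(train_ids), n_test = length(test_ids))
}
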