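#' Tidiers for regionage result objects
#'
#' broom-style [generics::tidy()] and [generics::glance()] methods: `tidy()`
#' returns the per-unit table of an object (per participant, per region, per
#' coefficient), `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name regionage-tidiers
NULL

#' @rdname regionage-tidiers
#' @method tidy brainage_result
#' @export
tidy.brainage_result <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname regionage-tidiers
#' @method glance brainage_result
#' @export
glance.brainage_result <- function(x, ...) {
  prediction_metrics(x)
}

#' @rdname regionage-tidiers
#' @method tidy region_clustering
#' @export
tidy.region_clustering <- function(x, ...) {
  x$assignment
}

#' @rdname regionage-tidiers
#' @method glance region_clustering
#' @export
glance.region_clustering <- function(x, ...) {
  tibble(k = x$k, n_regions = nrow(x$assignment),
         linkage = x$method$linkage, distance = x$method$distance)
}

#' @rdname regionage-tidiers
#' @method tidy parity_polyfit
#' @export
tidy.parity_polyfit <- function(x, ...) {
  bind_rows(
    tibble(model = "linear", term = "beta",
           estimate = x$linear$beta, std.error = x$linear$se),
    tibble(model = "quadratic", term = c("beta", "gamma"),
           estimate = c(x$quadratic$beta, x$quadratic$gamma),
           std.error = c(x$quadratic$beta_se, x$quadratic$gamma_se)),
    tibble(model = "orthogonal", term = c("beta", "gamma"),
           estimate = c(x$orthogonal$beta, x$orthogonal$gamma),
           std.error = c(x$orthogonal$beta_se, x$orthogonal$gamma_se))
  )
}

#' @rdname regionage-tidiers
#' @method glance parity_polyfit
#' @export
glance.parity_polyfit <- function(x, ...) {
  tibble(n_groups = nrow(x$groups),
         f_linear = x$f_linear$f, p_linear = x$f_linear$p,
         f_quadratic = x$f_quadratic$f, p_quadratic = x$f_quadratic$p,
         f_compare = x$f_compare, p_compare = x$p_compare)
}

#' @rdname regionage-tidiers
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  x$counts
}

#' @rdname regionage-tidiers
#' @method tidy parity_pipeline
#' @export
tidy.parity_pipeline <- function(x, ...) {
  bind_rows(x$associations, x$sub_associations)
}

#' @rdname regionage-tidiers
#' @method glance parity_pipeline
#' @export
glance.parity_pipeline <- function(x, ...) {
  tibble(
    total_n = x$qc_report$total_n, retained_n = x$qc_report$retained_n,
    k_top = x$clustering$k, k_sub = x$subclustering$k,
    strongest_cluster = x$strongest_cluster,
    strongest_subcluster = x$strongest_subcluster,
    engine = x$provenance$engine
  )
}
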