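#' Spearman rank-order correlation matrix of a feature table
#'
#' Pearson correlation of mid-ranked columns; invariant to strictly
#' monotone transforms of any column.
#'
#' @param features Feature tibble (`participant_id` optional) with at least
#'   3 rows and no constant column.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(features) {
  Y <- as.matrix(features[, setdiff(names(features), "participant_id"),
                          drop = FALSE])
  if (nrow(Y) < 3) abort("need at least 3 participants.")
  sds <- apply(Y, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant column(s): ",
                 paste(colnames(Y)[sds == 0], collapse = ", ")))
  }
  cor(Y, method = "spearman")
}

#' Hierarchical clustering of regions on a correlation matrix
#'
#' Agglomerative clustering with distance `1 - rho` and, by default,
#' average linkage; the tree is cut into exactly `k` clusters. Labels are
#' renumbered 1..k in order of first appearance so the partition is
#' deterministic given the inputs. `"ward"` (Ward.D2 on the correlation
#' distance) is available as an alternative linkage.
#'
#' @param corr Correlation matrix, e.g. from [spearman_matrix()].
#' @param k Number of clusters (1 to the number of regions).
#' @param linkage `"average"` (default), `"complete"`, or `"ward"`.
#' @return An object of class `"region_clustering"`: a list with
#'   `assignment` (tibble `region`, `cluster`), the `hclust` tree, `k`, and
#'   method metadata.
#' @export
hierarchical_clusters <- function(corr, k = 5,
                                  linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  p <- ncol(corr)
  if (k < 1 || k > p) abort("`k` must lie between 1 and the number of regions.")
  d <- as.dist(1 - corr)
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- hclust(d, method = method)
  raw <- cutree(tree, k = k)
  # contiguous labels in order of first appearance over the input columns
  labels <- as.integer(factor(raw, levels = unique(raw)))
  structure(
    list(
      assignment = tibble(region = colnames(corr), cluster = labels),
      tree = tree, k = as.integer(k),
      method = list(distance = "1 - spearman rho", linkage = linkage)
    ),
    class = "region_clustering"
  )
}

#' @export
print.region_clustering <- function(x, ...) {
  cat("Region clustering:", x$k, "clusters,", nrow(x$assignment),
      "regions (", x$method$linkage, "linkage on", x$method$distance, ")\n")
  print(table(cluster = x$assignment$cluster))
  invisible(x)
}

#' Re-cluster the members of one cluster
#'
#' Repeats the clustering procedure on the feature columns belonging to a
#' single parent cluster, e.g. to split the strongest-associated cluster
#' into sub-clusters.
#'
#' @param features Feature tibble the parent clustering was computed from.
#' @param parent A `"region_clustering"`.
#' @param cluster Parent cluster label to subdivide.
#' @param k Number of sub-clusters.
#' @inheritParams hierarchical_clusters
#' @return A `"region_clustering"` on the member regions only.
#' @export
subcluster <- function(features, parent, cluster, k = 2,
                       linkage = c("average", "complete", "ward")) {
  stopifnot(inherits(parent, "region_clustering"))
  members <- parent$assignment$region[parent$assignment$cluster == cluster]
  if (length(members) < k) {
    abort(paste0("cluster ", cluster, " has ", length(members),
                 " members; cannot form ", k, " sub-clusters."))
  }
  cols <- intersect(c("participant_id", members), names(features))
  hierarchical_clusters(
    spearman_matrix(features[, cols]),
    k = k, linkage = match.arg(linkage)
  )
}

#' Feature sets implied by a clustering
#'
#' @param clustering A `"region_clustering"`.
#' @return Named list mapping `"cluster_<label>"` to region-name vectors.
#' @export
cluster_feature_sets <- function(clustering) {
  split(clustering$assignment$region, clustering$assignment$cluster) %>%
    setNames(paste0("cluster_", sort(unique(clustering$assignment$cluster))))
}

#' Write a clustering to disk
#'
#' Assignment as two-column CSV; merge tree (heights and merge order) as
#' JSON.
#'
#' @param clustering A `"region_clustering"`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_clustering <- function(clustering, dir, prefix = "clusters") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(assignment = file.path(dir, paste0(prefix, ".csv")),
             linkage = file.path(dir, paste0(prefix, "_linkage.json")))
  utils::write.csv(clustering$assignment, paths["assignment"],
                   row.names = FALSE)
  jsonlite::write_json(
    list(merge = clustering$tree$merge, height = clustering$tree$height,
         labels = clustering$tree$labels, method = clustering$method,
         k = clustering$k),
    paths["linkage"], digits = NA, auto_unbox = TRUE
  )
  invisible(paths)
}
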