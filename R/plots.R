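# ggplot2 displays for the main result types.

# Segment coordinates of an hclust tree (leaves at y = 0, merges at their
# heights), for drawing dendrograms without extra dependencies.
dendro_segments <- function(tree) {
  m <- tree$merge
  h <- tree$height
  leaf_x <- match(seq_along(tree$labels), tree$order)
  node_x <- numeric(nrow(m))
  segs <- vector("list", nrow(m))
  child <- function(id) {
    if (id < 0) c(x = leaf_x[-id], y = 0) else c(x = node_x[id], y = h[id])
  }
  for (i in seq_len(nrow(m))) {
    a <- child(m[i, 1]); b <- child(m[i, 2])
    node_x[i] <- (a["x"] + b["x"]) / 2
    segs[[i]] <- tibble(
      x = c(a["x"], b["x"], a["x"]),
      xend = c(a["x"], b["x"], b["x"]),
      y = c(a["y"], b["y"], h[i]),
      yend = c(h[i], h[i], h[i])
    )
  }
  bind_rows(segs)
}

#' Dendrogram of a region clustering
#'
#' Leaves are the regions, coloured by cluster assignment; the y axis is
#' the merge distance (1 - Spearman rho), so lower joins mean stronger
#' collinearity.
#'
#' @param object A `"region_clustering"`.
#' @param label_size Leaf label text size.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot region_clustering
#' @export
autoplot.region_clustering <- function(object, label_size = 2.5, ...) {
  tree <- object$tree
  segs <- dendro_segments(tree)
  leaves <- tibble(
    x = seq_along(tree$order),
    region = tree$labels[tree$order]
  ) %>%
    left_join(object$assignment, by = "region")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend),
      linewidth = 0.3
    ) +
    ggplot2::geom_text(
      data = leaves,
      ggplot2::aes(x = .data$x, y = -0.01, label = .data$region,
                   colour = factor(.data$cluster)),
      angle = 90, hjust = 1, size = label_size
    ) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.35, 0.05))) +
    ggplot2::labs(x = NULL, y = "1 - Spearman rho", colour = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Group means and polynomial fits of delta versus exposure
#'
#' Points are the per-parity group means of age-corrected brain-age delta
#' with their standard errors; the lines are the degree-1 and degree-2
#' weighted least-squares fits.
#'
#' @param object A `"parity_polyfit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot parity_polyfit
#' @export
autoplot.parity_polyfit <- function(object, ...) {
  grid <- tibble(exposure = seq(min(object$groups$exposure),
                                max(object$groups$exposure),
                                length.out = 100))
  grid$linear <- predict(object$fit_linear, grid)
  grid$quadratic <- predict(object$fit_quadratic, grid)
  lines <- tidyr::pivot_longer(grid, c("linear", "quadratic"),
                               names_to = "fit", values_to = "mean")
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = .data$exposure, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(data = lines, ggplot2::aes(colour = .data$fit)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      width = 0.1
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of childbirths",
                  y = "brain-age delta (age-corrected, years)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Matrix of pairwise correlated-estimates Z tests
#'
#' Tile display of the pairwise Z statistics between feature-set
#' associations, annotated with the (FDR-adjusted) significance.
#'
#' @param comparisons Output of [pairwise_comparisons()].
#' @param q Significance threshold applied to `p_adj`.
#' @return A ggplot object.
#' @export
plot_comparison_matrix <- function(comparisons, q = 0.05) {
  df <- bind_rows(
    comparisons,
    comparisons %>% mutate(tmp = .data$set_1, set_1 = .data$set_2,
                           set_2 = .data$tmp, z = -.data$z) %>%
      select(-"tmp")
  )
  df$label <- sprintf("%.2f%s", df$z, ifelse(df$p_adj < q, "*", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set_1, y = .data$set_2,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z",
                  caption = paste0("* FDR-adjusted p < ", q)) +
    ggplot2::theme_minimal()
}
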