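#' Plot a community model as a composition heatmap
#'
#' Clusters (rows, labelled by their enriched classes if
#' [label_communities()] has run) against phenotype classes, tile fill
#' giving the mean profile fraction, with the cluster's share of all
#' cells alongside.
#'
#' @param object a `community_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.community_model <- function(object, ...) {
  df <- tidy(object)
  df$cluster_lab <- if ("label" %in% names(df)) {
    sprintf("%d: %s", df$cluster, df$label)
  } else as.character(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$phenotype, y = stats::reorder(.data$cluster_lab, .data$cluster),
    fill = .data$fraction
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "community cluster",
                  fill = "mean\nfraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot one FOV's cells, optionally highlighting flagged neighborhoods
#'
#' Scatter of cell centroids colored by phenotype; index cells whose
#' `cell_id` appears in `highlight` are circled (e.g. neighborhoods with
#' a PD1+ TIL neighbor).
#'
#' @param cells a cell table.
#' @param fov one `fov_id` to draw.
#' @param highlight optional character vector of `cell_id`s to circle.
#' @return a ggplot object.
#' @export
plot_fov <- function(cells, fov, highlight = NULL) {
  df <- cells[cells$fov_id == fov, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        color = .data$phenotype)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = fov, x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    hl <- df[df$cell_id %in% highlight, ]
    p <- p + ggplot2::geom_point(data = hl, shape = 21, size = 2.4,
                                 stroke = 0.8, color = "black", fill = NA)
  }
  p
}

#' Plot cohort comparisons
#'
#' Per-feature pooled event fractions by outcome group, faceted by
#' feature family if present, with significant features (BH-adjusted
#' p < alpha) marked.
#'
#' @param comparisons output of [compare_groups()] (optionally with a
#'   `family` column, as written by [run_pipeline()]).
#' @param alpha significance level used for the marks.
#' @return a ggplot object.
#' @export
plot_comparisons <- function(comparisons, alpha = 0.05) {
  frac_cols <- grep("^frac_", names(comparisons), value = TRUE)
  df <- tidyr::pivot_longer(comparisons,
                            dplyr::all_of(frac_cols),
                            names_to = "group", values_to = "fraction")
  df$group <- sub("^frac_", "", df$group)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$fraction, y = .data$feature, fill = .data$group
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_point(
      data = df[df$p_adj < alpha, ],
      ggplot2::aes(x = .data$fraction), shape = 8, size = 1.6,
      show.legend = FALSE
    ) +
    ggplot2::labs(x = "pooled event fraction", y = NULL, fill = "group") +
    ggplot2::theme_minimal()
  if ("family" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~family, scales = "free_y")
  }
  p
}
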