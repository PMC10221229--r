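# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an embedded chemical space
#'
#' Scatter of the first two embedding coordinates, optionally coloured
#' by a cluster assignment or any per-molecule labelling.
#'
#' @param object An `odor_embedding`.
#' @param colour_by Optional `cluster_assignment`, or a vector named by
#'   (or aligned with) molecule ids.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.odor_embedding <- function(object, colour_by = NULL, ...) {
  df <- tibble::as_tibble(object)
  cols <- setdiff(names(df), "id")[1:2]
  if (inherits(colour_by, "cluster_assignment")) {
    df$group <- factor(colour_by$cluster[match(df$id, colour_by$id)])
  } else if (!is.null(colour_by)) {
    df$group <- if (!is.null(names(colour_by))) {
      factor(colour_by[df$id])
    } else factor(colour_by)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[cols[1]]], .data[[cols[2]]])) +
    ggplot2::theme_minimal()
  if ("group" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 1) +
      ggplot2::labs(colour = NULL)
  } else {
    p + ggplot2::geom_point(size = 1)
  }
}

#' Elbow and Kelley-penalty curves
#'
#' @param object A `cluster_selection`.
#' @param ... Ignored.
#' @return A ggplot faceted into the within-cluster sum of squares
#'   (elbow) and penalty curves, with the optimum marked.
#' @export
autoplot.cluster_selection <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object)[c("k", "wss", "penalty")],
                            cols = c("wss", "penalty"),
                            names_to = "curve", values_to = "value")
  k_opt <- attr(object, "k_optimal")
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = k_opt, linetype = 2) +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = NULL, title = paste0("Optimal k = ", k_opt))
}

#' Radar-style odor profile of one cluster
#'
#' Polar bar chart of `pct_ON` (or `pct_OM`) over notes for a cluster,
#' the layout used for cluster odor-profile radar charts.
#'
#' @param stats A `note_cluster_stats` tibble.
#' @param cluster Cluster index to display.
#' @param value `"pct_ON"` or `"pct_OM"`.
#' @return A ggplot.
#' @export
plot_note_profile <- function(stats, cluster, value = c("pct_ON", "pct_OM")) {
  value <- match.arg(value)
  df <- stats[stats$cluster == cluster, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$note, .data[[value]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_polar() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 6)) +
    ggplot2::labs(x = NULL, y = value,
                  title = paste0("Cluster ", cluster))
}

#' Heatmap of relative note co-occurrences
#'
#' @param object A `cooc_matrices` object.
#' @param ... Ignored.
#' @return A ggplot tile map of the nonsymmetric relative matrix.
#' @export
autoplot.cooc_matrices <- function(object, ...) {
  df <- tibble::as_tibble(object$relative, rownames = "note")
  df <- tidyr::pivot_longer(df, -"note", names_to = "with",
                            values_to = "relative")
  df$note <- factor(df$note, levels = rev(object$notes))
  df$with <- factor(df$with, levels = object$notes)
  ggplot2::ggplot(df, ggplot2::aes(.data$with, .data$note,
                                   fill = .data$relative)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% of row note")
}
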