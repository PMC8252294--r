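#' Plot observed importances against their permutation nulls
#'
#' Dot-and-interval plot of each feature's mean importance with the
#' 95th/99th percentiles of its permutation-null distribution; selected
#' features are highlighted. Only the `n_top` highest-importance features
#' are shown.
#'
#' @param object An [rf_select()] result.
#' @param n_top Number of features to display (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rf_selection <- function(object, n_top = 20, ...) {
  res <- tidy(object)
  nulls <- object$nulls
  q <- apply(nulls, 2, quantile, probs = c(0.95, 0.99))
  d <- res %>%
    mutate(null_q95 = q[1, .data$feature], null_q99 = q[2, .data$feature]) %>%
    arrange(dplyr::desc(.data$mean_importance)) %>%
    utils::head(n_top) %>%
    mutate(feature = factor(.data$feature, levels = rev(.data$feature)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_importance,
                                  y = .data$feature)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$null_q95,
                                         xmax = .data$null_q99),
                            colour = "grey60", linewidth = 2, alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey30"),
                                 name = "selected") +
    ggplot2::labs(x = "mean feature importance",
                  y = NULL,
                  subtitle = "grey band: 95th-99th null percentile") +
    ggplot2::theme_minimal()
}

#' Heatmap of clustered feature abundances
#'
#' log10(x + 1) accession-mean abundances with features in complete-linkage
#' cluster order and accessions optionally ordered by a survival summary.
#'
#' @param ft A `feature_table`.
#' @param accession_order Optional character vector giving the accession
#'   display order (e.g. by ascending survival).
#' @return A ggplot object.
#' @export
plot_feature_heatmap <- function(ft, accession_order = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  clus <- cluster_features(ft)
  d <- ft$wide %>%
    tidyr::pivot_longer(-"accession", names_to = "feature",
                        values_to = "abundance") %>%
    mutate(log10_abundance = log10(.data$abundance + 1),
           feature = factor(.data$feature, levels = clus$order))
  if (!is.null(accession_order)) {
    d <- mutate(d, accession = factor(.data$accession,
                                      levels = accession_order))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$accession, y = .data$feature,
                                  fill = .data$log10_abundance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(abundance + 1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Abundance panel for selected metabolites
#'
#' Bar panel of log10-scaled mean abundances with delta-method standard
#' errors, one facet per selected feature, accessions in a supplied order
#' (typically ascending survival).
#'
#' @param report A [render_reports()] result with a non-empty
#'   `abundance_panel`.
#' @param accession_order Optional accession display order.
#' @return A ggplot object.
#' @export
plot_abundance_panel <- function(report, accession_order = NULL) {
  panel <- report$abundance_panel
  if (is.null(panel)) abort("No selected features to plot.")
  if (!is.null(accession_order)) {
    panel <- mutate(panel, accession = factor(.data$accession,
                                              levels = accession_order))
  }
  p <- ggplot2::ggplot(panel, ggplot2::aes(x = .data$accession,
                                           y = .data$log10_mean))
  if ("class" %in% names(panel)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$class))
  } else {
    p <- p + ggplot2::geom_col(fill = "grey40")
  }
  p +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$log10_mean - .data$log10_se,
                                        ymax = .data$log10_mean + .data$log10_se),
                           width = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "log10 mean abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Relative-survival scatter of the two insects
#'
#' @param data A data frame with columns `accession`, `whitefly`, `thrips`
#'   holding relative survival percentages.
#' @return A ggplot object.
#' @export
plot_survival_scatter <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$whitefly, y = .data$thrips,
                                     label = .data$accession)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "relative whitefly survival (%)",
                  y = "relative thrips survival (%)") +
    ggplot2::theme_minimal()
}
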