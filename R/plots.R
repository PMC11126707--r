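#' Heatmap of the input-flux Kendall correlation map
#'
#' @param object A `gmf_correlation` from [input_flux_correlation()].
#' @param ... Unused.
#' @return A ggplot: tiles colored by tau (blue negative, red positive),
#'   rows/columns in dendrogram order.
#' @exportS3Method ggplot2::autoplot
autoplot.gmf_correlation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flux_id, y = .data$input,
                                   fill = .data$tau)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$tau)),
                       size = 2.4) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Kendall tau") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bootstrap AUC distribution
#'
#' @param object An `auc_report` from [bootstrap_auc()].
#' @param ... Unused.
#' @return A ggplot histogram of the bootstrap AUCs with the median and
#'   percentile interval marked.
#' @exportS3Method ggplot2::autoplot
autoplot.auc_report <- function(object, ...) {
  df <- tibble(auc = object$aucs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = object$median, linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(object$ci_lower, object$ci_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Out-of-bag AUC", y = "Bootstrap iterations") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by risk group
#'
#' @param km Tidy curve tibble from [km_curves()].
#' @return A ggplot step plot of event-free survival per group.
#' @export
plot_km_curves <- function(km) {
  start <- km |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  df <- dplyr::bind_rows(start, km[, c("group", "time", "survival")]) |>
    dplyr::arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "CKD-free survival", color = NULL) +
    ggplot2::theme_minimal()
}

#' Cluster distance against CKD outcome rate
#'
#' @param object A `cluster_outcome` from [cluster_distance_outcome()].
#' @param ... Unused.
#' @return A ggplot scatter of per-cluster centroid distance (from the
#'   lowest-rate cluster) versus outcome rate, annotated with Kendall's tau.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_outcome <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$ckd_rate)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "grey40", fill = "grey85") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::labs(
      x = "Centroid distance from lowest-rate cluster",
      y = "CKD outcome rate",
      size = "Patients",
      subtitle = sprintf("Kendall tau = %.2f (p = %.3g)", object$tau,
                         object$p.value)
    ) +
    ggplot2::theme_minimal()
}

#' Risk stratification bar chart
#'
#' @param strat Tibble from [risk_outcome_table()].
#' @return A ggplot of observed CKD percentage per risk band with the
#'   expected medians overlaid.
#' @export
plot_risk_bands <- function(strat) {
  ggplot2::ggplot(strat, ggplot2::aes(x = .data$risk_group,
                                      y = .data$pct_ckd)) +
    ggplot2::geom_col(fill = "grey70", color = "grey30") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected_median_pct),
                        shape = 4, size = 3, stroke = 1.2) +
    ggplot2::labs(x = NULL, y = "% developing CKD",
                  caption = "crosses: expected band medians") +
    ggplot2::theme_minimal()
}
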