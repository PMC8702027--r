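#' Plot a concentration-response series with its fitted curve
#'
#' @param series Data frame with `dilution` and `response` (vehicle-scaled).
#' @param fit Optional [fit_logistic()] result; fitted if omitted.
#' @param vehicle_sd Optional vehicle band half-width to draw around 1.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(series, fit = fit_logistic(series),
                               vehicle_sd = NULL) {
  grid <- tibble::tibble(
    dilution = 10^seq(log10(min(series$dilution)),
                      log10(max(series$dilution)), length.out = 200)
  )
  grid$response <- predict(fit, grid$dilution)
  p <- ggplot2::ggplot(series, ggplot2::aes(dilution, response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, color = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dilution (fraction of extract stock)",
                  y = "vehicle-scaled response") +
    ggplot2::theme_minimal()
  if (!is.null(vehicle_sd)) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = 1 - vehicle_sd, ymax = 1 + vehicle_sd,
                               alpha = 0.15, fill = "steelblue")
  }
  p
}

#' Ranked overall ToxPi scores
#'
#' Bar chart of samples ordered by overall ToxPi score, colored by region
#' when `sites` is given.
#'
#' @param profiles A [toxpi_profiles()] result.
#' @param sites Optional site table with `region`.
#' @return A ggplot object.
#' @export
plot_toxpi_ranking <- function(profiles, sites = NULL) {
  df <- dplyr::arrange(tibble::as_tibble(profiles), .data$rank)
  df$sample_id <- factor(df$sample_id, levels = df$sample_id)
  if (!is.null(sites)) {
    df <- dplyr::left_join(df, dplyr::select(sites, sample_id, region),
                           by = "sample_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(sample_id, overall, fill = region))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(sample_id, overall))
  }
  p + ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "overall ToxPi score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Per-region distribution of overall ToxPi scores
#'
#' @param profiles A [toxpi_profiles()] result.
#' @param sites Site table with `region`.
#' @return A ggplot object (box = interquartile range, whiskers = min/max).
#' @export
plot_region_scores <- function(profiles, sites) {
  df <- dplyr::left_join(
    dplyr::select(tibble::as_tibble(profiles), sample_id, overall),
    dplyr::select(sites, sample_id, region), by = "sample_id"
  )
  ggplot2::ggplot(df, ggplot2::aes(region, overall, fill = region)) +
    ggplot2::geom_boxplot(coef = Inf, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "overall ToxPi score") +
    ggplot2::theme_minimal()
}

#' @describeIn krige Raster map of the kriged surface with site overlay.
#' @param object A `sed_krige`.
#' @param ... Unused.
#' @export
autoplot.sed_krige <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(lon, lat)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$pred)) +
    ggplot2::geom_point(data = object$sites, shape = 21, fill = "white") +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(fill = if (object$log_transform) "log10 value" else "value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Remediation dumbbell plot
#'
#' Baseline vs post-remediation values per sample for the two panels of the
#' remediation comparison (residual bioactivity after traditional cleanup;
#' residual cancer risk after bioactivity-based cleanup), with the target
#' thresholds as dashed lines.
#'
#' @param rem A [remediation_table()] result.
#' @return A ggplot object.
#' @export
plot_remediation_dumbbell <- function(rem) {
  db <- remediation_dumbbell(rem)
  db$sample_id <- stats::reorder(db$sample_id, db$baseline)
  ggplot2::ggplot(db, ggplot2::aes(y = sample_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$remediated,
                                       xend = .data$baseline,
                                       yend = sample_id),
                          color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$baseline),
                        shape = 21, color = "firebrick", fill = NA) +
    ggplot2::geom_point(ggplot2::aes(x = .data$remediated,
                                     color = .data$meets_target)) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$target),
                        linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "forestgreen",
                                           `FALSE` = "firebrick"),
                                name = "meets target") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}
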