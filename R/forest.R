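# Forest plots of user-supplied ratio-scale summaries (hazard or odds ratios
# with confidence intervals). Intervals are plotted verbatim; nothing is
# recomputed or pooled.

#' Forest plot of hazard/odds ratios with confidence intervals
#'
#' One row per input row, in input order (top to bottom, no sorting): a point
#' at the estimate, a whisker spanning `[lower, upper]`, and a vertical
#' reference line (1.0 by default). The axis is log-scaled by default, the
#' natural scale for ratio measures.
#'
#' @param rows Forest table (`label`, `estimate`, `lower`, `upper`), e.g. from
#'   [read_forest_table()]; validated before plotting.
#' @param title Plot title.
#' @param axis_label Horizontal axis label.
#' @param font_size Base font size in points.
#' @param point_color,ci_color Colors for the point estimates and whiskers.
#' @param log_scale Log-scale the ratio axis.
#' @param reference_line Position of the vertical reference line (must be
#'   positive when `log_scale`).
#' @return A ggplot object.
#' @export
plot_forest <- function(rows, title = "", axis_label = "Hazard / odds ratio",
                        font_size = 11, point_color = "black", ci_color = "black",
                        log_scale = TRUE, reference_line = 1) {
  rows <- validate_forest_rows(rows)
  if (!is.numeric(font_size) || font_size <= 0) stop_superpca("font_size must be positive")
  if (log_scale && reference_line <= 0) {
    stop_superpca("reference_line must be positive on a log scale")
  }
  d <- dplyr::mutate(rows, .row = factor(dplyr::row_number(),
                                         levels = rev(seq_len(nrow(rows)))))
  gp <- ggplot2::ggplot(d, ggplot2::aes(y = .data$.row)) +
    ggplot2::geom_vline(xintercept = reference_line, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
                            height = 0.25, colour = ci_color) +
    ggplot2::geom_point(ggplot2::aes(x = .data$estimate), colour = point_color, size = 2) +
    ggplot2::scale_y_discrete(labels = stats::setNames(d$label, as.character(d$.row))) +
    ggplot2::labs(x = axis_label, y = NULL, title = if (nzchar(title)) title else NULL) +
    ggplot2::theme_minimal(base_size = font_size) +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank())
  if (log_scale) gp <- gp + ggplot2::scale_x_log10()
  gp
}

#' Write a forest plot to file
#'
#' Validates every row before anything is written; the output format follows
#' the file extension (`.png`, `.svg` or `.pdf`).
#'
#' @inheritParams plot_forest
#' @param out_path Output path.
#' @param width,height Device size in inches.
#' @return `out_path`, invisibly.
#' @export
render_forest <- function(rows, out_path, title = "",
                          axis_label = "Hazard / odds ratio", font_size = 11,
                          point_color = "black", ci_color = "black",
                          log_scale = TRUE, reference_line = 1,
                          width = 6, height = NULL) {
  rows <- validate_forest_rows(rows)
  ext <- tolower(sub(".*\\.", "", out_path))
  if (!ext %in% c("png", "svg", "pdf")) {
    stop_superpca("unsupported output format '.", ext, "'; supported: png, svg, pdf")
  }
  gp <- plot_forest(rows, title = title, axis_label = axis_label,
                    font_size = font_size, point_color = point_color,
                    ci_color = ci_color, log_scale = log_scale,
                    reference_line = reference_line)
  height <- height %||% max(2, 0.8 + 0.35 * nrow(rows))
  switch(ext,
    png = grDevices::png(out_path, width = width, height = height, units = "in", res = 150),
    svg = grDevices::svg(out_path, width = width, height = height),
    pdf = grDevices::pdf(out_path, width = width, height = height))
  print(gp)
  grDevices::dev.off()
  invisible(out_path)
}
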