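# ggplot2 views of diagnostics tables and comparisons.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Residual-versus-prediction plot for a diagnostics table
#'
#' Scatter of a residual column against IPRED with guide lines at 0 and +/-2,
#' the standard individual-diagnostic view.
#'
#' @param object An `nm_diag` tibble.
#' @param residual Column to plot: `"IWRES"`, `"CWRESI"` or `"WRES"`.
#' @param log_x Use a log10 x axis (useful for proportional-error runs).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nm_diag
#' @export
autoplot.nm_diag <- function(object, residual = c("IWRES", "CWRESI", "WRES"),
                             log_x = FALSE, ...) {
  residual <- match.arg(residual)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$IPRED, y = .data[[residual]])) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = "IPRED (mg/L)", y = residual,
      title = paste0(attr(object, "coding_id") %||% "", " ", residual, " vs IPRED")
    ) +
    ggplot2::theme_bw()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' IWRES-ratio view of a pairwise comparison
#'
#' Per-observation IWRES ratio (B/A) against the reference IPRED, with
#' extreme-ratio rows (`|ratio| > threshold`) highlighted.
#'
#' @param object A [compare_runs()] result.
#' @param threshold Extreme-ratio threshold.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot resid_comparison
#' @export
autoplot.resid_comparison <- function(object, threshold = 5, ...) {
  rows <- attr(object, "rows")
  rows$extreme <- !is.na(rows$ratio) & abs(rows$ratio) > threshold
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$IPRED_a, y = .data$ratio)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$extreme, colour = .data$extreme),
      alpha = 0.5, size = 1
    ) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 2)) +
    ggplot2::labs(
      x = "IPRED, reference run (mg/L)",
      y = paste0("IWRES ratio ", object$run_b, " / ", object$run_a)
    ) +
    ggplot2::theme_bw()
}

#' Overlay residuals from two runs
#'
#' Superimposes residual-versus-IPRED scatter from two diagnostics tables —
#' the cross-run view in which inconsistent W definitions produce apparent
#' (artifactual) differences in residual dispersion.
#'
#' @param table_a,table_b `nm_diag` tibbles.
#' @param residual Column to plot.
#' @param labels Length-2 legend labels; defaults to the coding ids.
#' @return A ggplot object.
#' @export
plot_resid_overlay <- function(table_a, table_b, residual = "IWRES", labels = NULL) {
  if (is.null(labels)) {
    labels <- c(
      attr(table_a, "coding_id") %||% "run A",
      attr(table_b, "coding_id") %||% "run B"
    )
  }
  dat <- dplyr::bind_rows(
    tibble::tibble(run = labels[1], IPRED = table_a$IPRED, residual = table_a[[residual]]),
    tibble::tibble(run = labels[2], IPRED = table_b$IPRED, residual = table_b[[residual]])
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$IPRED, y = .data$residual, colour = .data$run)) +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "IPRED (mg/L)", y = residual, colour = NULL) +
    ggplot2::theme_bw()
}
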