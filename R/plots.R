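# Reporting figures: IRR exposure-response panels and smoothed PAF trend
# panels.  ggplot2 is an optional dependency; both functions error with a
# clear message when it is unavailable.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
}

#' Plot an IRR exposure-response curve
#'
#' The estimate with its pointwise band, a horizontal line at IRR 1, a
#' vertical line at the reference (mean) exposure, and shading over grid
#' points whose interval excludes 1.
#'
#' @param curve An [irr_curve()].
#' @return A ggplot object.
#' @export
plot_irr_curve <- function(curve) {
  need_ggplot()
  stopifnot(inherits(curve, "irr_curve"))
  df <- as.data.frame(curve)
  ggplot2::ggplot(df, ggplot2::aes(x = grid_value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                         fill = "grey80") +
    ggplot2::geom_ribbon(
      data = df[df$significant, , drop = FALSE],
      ggplot2::aes(ymin = lo, ymax = hi),
      fill = "lightblue") +
    ggplot2::geom_line(ggplot2::aes(y = irr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_vline(xintercept = attr(curve, "reference_value"),
                        colour = "orange") +
    ggplot2::labs(x = df$exposure[1],
                  y = sprintf("IRR (lag %d)", df$lag[1]))
}

#' Plot a smoothed PAF trend curve
#'
#' @param curve A [smooth_paf()] result.
#' @param points Optional [paf_series()] with aligned exposure values to
#'   overlay as points (columns `x`, `paf_pct`).
#' @return A ggplot object.
#' @export
plot_paf_curve <- function(curve, points = NULL) {
  need_ggplot()
  stopifnot(inherits(curve, "paf_curve"))
  df <- as.data.frame(curve)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = grid_value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = paf_trend)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = attr(curve, "exposure"),
                  y = sprintf("PAF %% (lag %d)", attr(curve, "lag")))
  if (!is.null(points))
    p <- p + ggplot2::geom_point(
      data = points, ggplot2::aes(x = x, y = paf_pct),
      alpha = 0.3, size = 0.6)
  p
}
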