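#' Plot a calibrated autoregulation curve with its threshold band
#'
#' Draws the fitted cubic over its fit domain, the baseline anchor, and the
#' lower/upper flow thresholds; if limits are supplied their pressures are
#' marked. Intended for the standard display of a group or animal curve.
#'
#' @param x A calibrated `autoreg_curve`.
#' @param limits Optional `autoreg_limits` for the same curve.
#' @param trace Optional [flow_trace()] scatter to underlay (values are
#'   rescaled by the curve's calibration factor).
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.autoreg_curve <- function(x, limits = NULL, trace = NULL, ...) {
  if (!identical(x$unit, "absolute"))
    stop("plotting expects a calibrated curve")
  bp <- seq(x$fit_domain[1], x$fit_domain[2], length.out = 400)
  flow <- predict(x, bp)
  ylim <- range(flow, if (!is.null(trace))
    x$calibration_factor * trace$cbf_au)
  plot(bp, flow, type = "l", lwd = 2,
       xlab = "Mean arterial pressure (mmHg)",
       ylab = "CBF (ml/100 g/min)", ylim = ylim, ...)
  if (!is.null(trace))
    graphics::points(trace$map_mmHg, x$calibration_factor * trace$cbf_au,
                     pch = 16, cex = 0.5, col = "grey50")
  graphics::points(x$baseline_bp, x$baseline_cbf_abs, pch = 19, col = "red")
  if (!is.null(limits)) {
    graphics::abline(h = c(limits$lower_cbf_threshold,
                           limits$upper_cbf_threshold),
                     lty = 3, col = "blue")
    usable <- c(if (!limits$lower_censored) limits$lower_bp,
                if (!limits$upper_censored) limits$upper_bp)
    if (length(usable))
      graphics::abline(v = usable, lty = 2, col = "blue")
  }
  invisible(x)
}
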