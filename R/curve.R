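#' Fit the MAP--CBF relationship with a cubic polynomial
#'
#' Ordinary least-squares fit of relative flow against mean arterial
#' pressure with a third-order polynomial, the standard static description
#' of the autoregulatory curve. The fitted curve is only trusted over the
#' pressure range actually sampled (`fit_domain`); a cubic diverges quickly
#' outside its data.
#'
#' Eligibility gates: at least 8 samples, a pressure span of at least
#' 60 mmHg, and at least `degree + 1` distinct pressures (otherwise the
#' design matrix is rank-deficient and the fit is refused). A narrow sweep
#' cannot express a triphasic shape, so short or narrow traces are rejected
#' rather than silently fitted.
#'
#' @param trace A [flow_trace()].
#' @param degree Polynomial degree; fixed at 3 for the analysis, exposed
#'   only for sensitivity checks.
#' @param min_span Minimum pressure span (mmHg) for eligibility.
#' @return An object of class `autoreg_curve` with unit `"arbitrary"`:
#'   coefficients `c0..c3` (intercept first), `fit_domain`, sample size and
#'   residual sum of squares.
#' @export
fit_curve <- function(trace, degree = 3, min_span = 60) {
  stopifnot(inherits(trace, "flow_trace"))
  if (degree < 1) stop("`degree` must be >= 1")
  map <- trace$map_mmHg
  cbf <- trace$cbf_au
  if (nrow(trace) < 8)
    stop("fitting requires at least 8 samples")
  span <- max(map) - min(map)
  if (span < min_span)
    stop(sprintf("pressure span %.1f mmHg is below the %.0f mmHg eligibility gate",
                 span, min_span))
  if (length(unique(map)) < degree + 1)
    stop(sprintf("degenerate fit: need at least %d distinct pressures", degree + 1))
  X <- outer(map, 0:degree, `^`)
  fit <- stats::lm.fit(X, cbf)
  if (fit$rank < degree + 1)
    stop("degenerate fit: rank-deficient design matrix")
  coefs <- unname(fit$coefficients)
  structure(
    list(coefficients = coefs,
         degree = degree,
         unit = "arbitrary",
         calibration_factor = NULL,
         baseline_bp = NULL,
         baseline_cbf_abs = NULL,
         fit_domain = c(min(map), max(map)),
         n = nrow(trace),
         rss = sum(fit$residuals^2),
         animal_id = attr(trace, "animal_id"),
         group = attr(trace, "group")),
    class = "autoreg_curve")
}

#' Evaluate a fitted autoregulation curve
#'
#' @param object An `autoreg_curve`.
#' @param bp Pressures (mmHg) at which to evaluate the polynomial.
#' @param ... Unused.
#' @return Numeric vector of flows (a.u. or ml/100 g/min depending on the
#'   curve's unit).
#' @export
predict.autoreg_curve <- function(object, bp, ...) {
  stopifnot(is.numeric(bp))
  drop(outer(bp, seq_along(object$coefficients) - 1, `^`) %*%
         object$coefficients)
}

#' @export
print.autoreg_curve <- function(x, ...) {
  cat(sprintf("Autoregulation curve (%s units), degree %d\n", x$unit, x$degree))
  cat("  coefficients:", format(x$coefficients, digits = 4), "\n")
  cat(sprintf("  fit domain: %.1f-%.1f mmHg, n = %d\n",
              x$fit_domain[1], x$fit_domain[2], x$n))
  if (identical(x$unit, "absolute"))
    cat(sprintf("  calibrated: %.4g (ml/100 g/min)/a.u. at %.1f mmHg -> %.1f ml/100 g/min\n",
                x$calibration_factor, x$baseline_bp, x$baseline_cbf_abs))
  invisible(x)
}

#' Calibrate an arbitrary-unit curve to absolute flow
#'
#' Laser-Doppler flowmetry reports relative flow only; absolute units come
#' from microsphere perfusion measured at baseline blood pressure in
#' separately instrumented animals. Calibration rescales the fitted curve so
#' that its value at `baseline_bp` equals the microsphere baseline flow:
#' the factor is `k = baseline_cbf_abs / curve(baseline_bp)` and every
#' polynomial coefficient is multiplied by `k`. The per-animal
#' arbitrary-unit gain cancels exactly in this step.
#'
#' @param curve An `autoreg_curve` with unit `"arbitrary"`.
#' @param baseline_cbf_abs Absolute baseline flow (ml/100 g/min), positive.
#' @param baseline_bp Baseline pressure (mmHg); must lie inside the curve's
#'   fit domain (no extrapolated calibration).
#' @return The calibrated `autoreg_curve` (unit `"absolute"`).
#' @export
calibrate <- function(curve, baseline_cbf_abs, baseline_bp) {
  stopifnot(inherits(curve, "autoreg_curve"))
  if (!identical(curve$unit, "arbitrary"))
    stop("`curve` is already calibrated")
  if (baseline_cbf_abs <= 0)
    stop("`baseline_cbf_abs` must be positive (ml/100 g/min)")
  if (baseline_bp < curve$fit_domain[1] || baseline_bp > curve$fit_domain[2])
    stop(sprintf("baseline_bp %.1f mmHg lies outside the fit domain [%.1f, %.1f]: refusing to extrapolate",
                 baseline_bp, curve$fit_domain[1], curve$fit_domain[2]))
  at_base <- predict(curve, baseline_bp)
  if (at_base <= 0)
    stop("curve value at baseline_bp is not positive: cannot calibrate")
  k <- baseline_cbf_abs / at_base
  curve$coefficients <- k * curve$coefficients
  curve$rss <- k^2 * curve$rss
  curve$unit <- "absolute"
  curve$calibration_factor <- k
  curve$baseline_bp <- baseline_bp
  curve$baseline_cbf_abs <- baseline_cbf_abs
  curve
}

#' Flow thresholds bounding the autoregulatory band
#'
#' Autoregulation is operationally defined as flow staying within a fixed
#' fraction (default +/-20%) of baseline flow, so the band is bounded by
#' `(1 - fraction)` and `(1 + fraction)` times baseline.
#'
#' @param baseline_cbf_abs Baseline absolute flow (ml/100 g/min), positive.
#' @param fraction Band half-width as a fraction of baseline, in (0, 1).
#' @return Named numeric vector `c(lower = ..., upper = ...)`.
#' @examples
#' compute_thresholds(100, 0.20)  # c(lower = 80, upper = 120)
#' @export
compute_thresholds <- function(baseline_cbf_abs, fraction = 0.20) {
  if (baseline_cbf_abs <= 0) stop("`baseline_cbf_abs` must be positive")
  if (fraction < 0 || fraction >= 1) stop("`fraction` must be in [0, 1)")
  c(lower = (1 - fraction) * baseline_cbf_abs,
    upper = (1 + fraction) * baseline_cbf_abs)
}

# real roots of a polynomial (coefficients ascending), via polyroot with a
# bracketed-bisection fallback over the given interval
real_roots <- function(coefs, interval) {
  # trim negligible leading (highest-order) coefficients so polyroot sees
  # the true degree
  scale <- max(abs(coefs))
  if (scale == 0) return(numeric(0))
  keep <- max(which(abs(coefs) > 1e-12 * scale))
  if (keep < 2) return(numeric(0))
  roots <- tryCatch(polyroot(coefs[seq_len(keep)]), error = function(e) NULL)
  if (!is.null(roots)) {
    re <- Re(roots)[abs(Im(roots)) < 1e-6 * pmax(1, abs(Re(roots)))]
  } else {
    re <- numeric(0)
  }
  # fallback / supplement: bisection on sign changes over a coarse grid
  grid <- seq(interval[1], interval[2], length.out = 512)
  vals <- drop(outer(grid, seq_along(coefs) - 1, `^`) %*% coefs)
  ch <- which(diff(sign(vals)) != 0)
  for (i in ch) {
    r <- stats::uniroot(function(x)
      drop(outer(x, seq_along(coefs) - 1, `^`) %*% coefs),
      c(grid[i], grid[i + 1]), tol = 1e-10)$root
    if (!length(re) || min(abs(re - r)) > 1e-6) re <- c(re, r)
  }
  sort(re[re >= interval[1] & re <= interval[2]])
}

#' Autoregulatory blood-pressure limits from a calibrated curve
#'
#' Solves the calibrated cubic for its crossings with the lower and upper
#' flow thresholds. The lower limit is the largest pressure strictly below
#' `baseline_bp` where the curve equals the lower threshold; the upper limit
#' is the smallest pressure strictly above `baseline_bp` where the curve
#' equals the upper threshold (first crossing walking away from baseline).
#' Roots are obtained analytically from the polynomial, with a bracketed
#' bisection fallback, and are restricted to the fit domain: a crossing that
#' would fall outside the measured pressure range is censored at the domain
#' edge and flagged rather than extrapolated.
#'
#' @param curve A calibrated `autoreg_curve` (unit `"absolute"`).
#' @param thresholds Named vector from [compute_thresholds()]; defaults to
#'   the +/-`fraction` band around the curve's baseline flow.
#' @param baseline_bp Baseline pressure; defaults to the curve's calibration
#'   anchor.
#' @param fraction Band half-width used when `thresholds` is not supplied.
#' @return An object of class `autoreg_limits` with fields `lower_bp`,
#'   `upper_bp`, `range_width` (NA when censored), the flow thresholds,
#'   `fraction` and censoring flags.
#' @export
find_limits <- function(curve, thresholds = NULL, baseline_bp = NULL,
                        fraction = 0.20) {
  stopifnot(inherits(curve, "autoreg_curve"))
  if (!identical(curve$unit, "absolute"))
    stop("`curve` must be calibrated to absolute units first")
  if (is.null(baseline_bp)) baseline_bp <- curve$baseline_bp
  if (is.null(thresholds))
    thresholds <- compute_thresholds(curve$baseline_cbf_abs, fraction)
  lo_thr <- unname(thresholds["lower"])
  hi_thr <- unname(thresholds["upper"])
  dom <- curve$fit_domain

  lo_roots <- real_roots(curve$coefficients - c(lo_thr, rep(0, curve$degree)),
                         dom)
  hi_roots <- real_roots(curve$coefficients - c(hi_thr, rep(0, curve$degree)),
                         dom)
  lo_roots <- lo_roots[lo_roots < baseline_bp]
  hi_roots <- hi_roots[hi_roots > baseline_bp]

  lower_censored <- length(lo_roots) == 0
  upper_censored <- length(hi_roots) == 0
  lower_bp <- if (lower_censored) dom[1] else max(lo_roots)
  upper_bp <- if (upper_censored) dom[2] else min(hi_roots)
  range_width <- if (lower_censored || upper_censored) NA_real_
                 else upper_bp - lower_bp

  structure(
    list(lower_bp = lower_bp,
         upper_bp = upper_bp,
         range_width = range_width,
         lower_cbf_threshold = lo_thr,
         upper_cbf_threshold = hi_thr,
         fraction = fraction,
         lower_censored = lower_censored,
         upper_censored = upper_censored,
         baseline_bp = baseline_bp,
         baseline_cbf_abs = curve$baseline_cbf_abs,
         animal_id = curve$animal_id,
         group = curve$group),
    class = "autoreg_limits")
}

#' @export
print.autoreg_limits <- function(x, ...) {
  fmt <- function(v, cens) if (cens) sprintf("%.1f (censored)", v)
                           else sprintf("%.1f", v)
  cat(sprintf("Autoregulatory limits (%s, %s):\n",
              x$animal_id %||% "?", x$group %||% "?"))
  cat(sprintf("  lower %s mmHg, upper %s mmHg, range %s mmHg\n",
              fmt(x$lower_bp, x$lower_censored),
              fmt(x$upper_bp, x$upper_censored),
              if (is.na(x$range_width)) "undefined"
              else sprintf("%.1f", x$range_width)))
  cat(sprintf("  flow band: %.1f-%.1f ml/100 g/min (+/-%.0f%% of %.1f)\n",
              x$lower_cbf_threshold, x$upper_cbf_threshold,
              100 * x$fraction, x$baseline_cbf_abs))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Width of the autoregulatory blood-pressure range
#'
#' The difference between the upper and lower autoregulatory limits, in
#' mmHg. With one or both limits censored the range is undefined and
#' `NA_real_` is returned (with a warning), never an extrapolated number.
#'
#' @param limits An `autoreg_limits` object, or the lower limit (mmHg) as a
#'   number.
#' @param upper_bp Upper limit (mmHg) when `limits` is given numerically.
#' @return Range width in mmHg, or `NA_real_` when undefined.
#' @examples
#' autoreg_range(77.3, 135.0)  # 57.7
#' @export
autoreg_range <- function(limits, upper_bp = NULL) {
  if (inherits(limits, "autoreg_limits")) {
    if (limits$lower_censored || limits$upper_censored) {
      warning("range undefined: one or both limits are censored")
      return(NA_real_)
    }
    return(limits$upper_bp - limits$lower_bp)
  }
  if (is.null(upper_bp))
    stop("supply an `autoreg_limits` object or both limits as numbers")
  stopifnot(is.numeric(limits), is.numeric(upper_bp))
  upper_bp - limits
}

#' Percent change in flow relative to a reference
#'
#' Expresses a test flow as a percent decrease from a reference flow:
#' positive values are decreases (e.g. 174.8 -> 116.9 is a 33.1% reduction),
#' negative values are increases.
#'
#' @param reference_flow Reference absolute flow (positive).
#' @param test_flow Test absolute flow.
#' @return `100 * (reference_flow - test_flow) / reference_flow`.
#' @export
percent_change <- function(reference_flow, test_flow) {
  if (any(reference_flow <= 0))
    stop("`reference_flow` must be positive")
  100 * (reference_flow - test_flow) / reference_flow
}
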