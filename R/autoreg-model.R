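#' Triphasic ground-truth autoregulation model
#'
#' Constructs the generating model used by the synthetic-data module: a
#' pressure--flow relationship that is linear (in fractional-flow terms) below
#' the lower plateau knee, flat at `plateau_flow` across the plateau, and
#' linear again above the upper knee. Each knee kink can be smoothed over
#' `blend_width` mmHg by ramping the limb slope with a cosine profile
#' (a smoothed hinge), so the curve is continuously differentiable and
#' non-decreasing -- the shape a low-order polynomial fit can reasonably
#' approximate.
#'
#' Fractional flow relative to the plateau is
#' \deqn{f(p) = 1 - s_b (L - p) \quad (p < L), \qquad
#'       f(p) = 1 \quad (L \le p \le U), \qquad
#'       f(p) = 1 + s_a (p - U) \quad (p > U),}
#' with `L`, `U` the knee pressures and `s_b`, `s_a` the fractional slopes
#' per mmHg; absolute flow is `plateau_flow * f(p)`.
#'
#' @param plateau_flow Absolute cerebral blood flow on the plateau
#'   (ml/100 g/min); must be positive.
#' @param lower_limit_bp,upper_limit_bp Plateau knee pressures (mmHg),
#'   `lower_limit_bp < upper_limit_bp`.
#' @param slope_below,slope_above Fractional flow change per mmHg on the
#'   hypotensive and hypertensive limbs; both must be positive.
#' @param blend_width Half-width (mmHg) of the cosine smoothing zone around
#'   each knee; `0` gives the exact piecewise-linear shape.
#'
#' @return An object of class `autoreg_model`.
#' @seealso [evaluate_true_model()], [true_autoreg_limits()],
#'   [simulate_trace()]
#' @examples
#' m <- autoreg_model(plateau_flow = 174.8, lower_limit_bp = 77.3,
#'                    upper_limit_bp = 135.0)
#' evaluate_true_model(m, c(60, 100, 160))
#' @export
autoreg_model <- function(plateau_flow,
                          lower_limit_bp,
                          upper_limit_bp,
                          slope_below = 0.015,
                          slope_above = 0.020,
                          blend_width = 5) {
  stopifnot(is.numeric(plateau_flow), length(plateau_flow) == 1L,
            is.numeric(lower_limit_bp), length(lower_limit_bp) == 1L,
            is.numeric(upper_limit_bp), length(upper_limit_bp) == 1L)
  if (!is.finite(plateau_flow) || plateau_flow <= 0)
    stop("`plateau_flow` must be a positive, finite flow (ml/100 g/min)")
  if (lower_limit_bp >= upper_limit_bp)
    stop("`lower_limit_bp` must be strictly below `upper_limit_bp`")
  if (slope_below <= 0 || slope_above <= 0)
    stop("limb slopes must be positive (fractional flow change per mmHg)")
  if (blend_width < 0)
    stop("`blend_width` must be non-negative (mmHg)")
  if (2 * blend_width > upper_limit_bp - lower_limit_bp)
    stop("blend zones overlap: `blend_width` exceeds half the plateau width")
  structure(
    list(plateau_flow = plateau_flow,
         lower_limit_bp = lower_limit_bp,
         upper_limit_bp = upper_limit_bp,
         slope_below = slope_below,
         slope_above = slope_above,
         blend_width = blend_width),
    class = "autoreg_model")
}

#' @export
print.autoreg_model <- function(x, ...) {
  cat("Triphasic autoregulation model\n")
  cat(sprintf("  plateau: %.1f ml/100 g/min over %.1f-%.1f mmHg\n",
              x$plateau_flow, x$lower_limit_bp, x$upper_limit_bp))
  cat(sprintf("  limb slopes: %.3f (below) / %.3f (above) per mmHg; blend %.1f mmHg\n",
              x$slope_below, x$slope_above, x$blend_width))
  invisible(x)
}

# smoothed hinge: max(u, 0) with the kink replaced, over |u| < bw, by the
# integral of a cosine smoothstep so the derivative rises smoothly 0 -> 1;
# non-decreasing everywhere, exact outside the blend zone
smooth_hinge <- function(u, bw) {
  if (bw == 0) return(pmax(u, 0))
  t <- pmin(pmax((u + bw) / (2 * bw), 0), 1)
  out <- bw * t - (bw / pi) * sin(pi * t)
  out[u > bw] <- u[u > bw]
  out
}

#' Evaluate the triphasic model at given pressures
#'
#' Returns absolute flow (ml/100 g/min) of an [autoreg_model()] at one or
#' more mean arterial pressures. Within the plateau (outside the blend
#' zones) the value is exactly `plateau_flow`; the function is continuous
#' and non-decreasing in pressure everywhere.
#'
#' @param model An [autoreg_model()].
#' @param bp Mean arterial pressure(s), mmHg; all must be positive.
#' @return Numeric vector of flows, same length as `bp`.
#' @examples
#' m <- autoreg_model(100, 80, 130, slope_below = 0.02, blend_width = 0)
#' evaluate_true_model(m, 60)  # 100 * (1 - 0.02 * 20) = 60
#' @export
evaluate_true_model <- function(model, bp) {
  stopifnot(inherits(model, "autoreg_model"), is.numeric(bp))
  if (any(!is.finite(bp)) || any(bp <= 0))
    stop("`bp` must be positive, finite pressures (mmHg)")
  bw <- model$blend_width
  f <- 1 -
    model$slope_below * smooth_hinge(model$lower_limit_bp - bp, bw) +
    model$slope_above * smooth_hinge(bp - model$upper_limit_bp, bw)
  model$plateau_flow * f
}

#' Ground-truth autoregulatory limits of a triphasic model
#'
#' The measurement procedure defines the autoregulatory limits as the
#' pressures where the pressure--flow curve crosses (1 - fraction) and
#' (1 + fraction) times baseline flow. Applied to the generating model
#' itself, those crossings are the ground truth that a fitted curve should
#' recover; they lie outside the plateau knees by about `fraction/slope`
#' mmHg. Crossings are found by bracketed root-finding on the true curve.
#'
#' @param model An [autoreg_model()].
#' @param fraction Flow band half-width as a fraction of baseline
#'   (default 0.20).
#' @param baseline_flow Baseline absolute flow anchoring the band; defaults
#'   to the model's plateau flow.
#' @return Named numeric vector `c(lower_bp, upper_bp)` in mmHg.
#' @export
true_autoreg_limits <- function(model, fraction = 0.20,
                                baseline_flow = model$plateau_flow) {
  stopifnot(inherits(model, "autoreg_model"))
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must be in (0, 1)")
  if (baseline_flow <= 0) stop("`baseline_flow` must be positive")
  lo_thr <- (1 - fraction) * baseline_flow
  hi_thr <- (1 + fraction) * baseline_flow
  L <- model$lower_limit_bp
  U <- model$upper_limit_bp
  bw <- model$blend_width
  # bracket each crossing around its position on the un-blended limb
  lo_guess <- L - (1 - lo_thr / model$plateau_flow) / model$slope_below
  hi_guess <- U + (hi_thr / model$plateau_flow - 1) / model$slope_above
  lo_bracket <- c(max(1e-6, lo_guess - bw - 1), L + bw)
  hi_bracket <- c(U - bw, hi_guess + bw + 1)
  # the curve is non-decreasing so each crossing is upward; extendInt guards
  # brackets when baseline_flow differs from the plateau flow
  lower <- stats::uniroot(function(p) evaluate_true_model(model, p) - lo_thr,
                          interval = lo_bracket, extendInt = "upX",
                          tol = 1e-10)$root
  upper <- stats::uniroot(function(p) evaluate_true_model(model, p) - hi_thr,
                          interval = hi_bracket, extendInt = "upX",
                          tol = 1e-10)$root
  c(lower_bp = lower, upper_bp = upper)
}
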