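# shared fixtures: control-like generating model, clean traces, and small
# microsphere record tables built in code

control_model <- function(blend_width = 5)
  autoreg_model(plateau_flow = 174.8, lower_limit_bp = 77.3,
                upper_limit_bp = 135.0, blend_width = blend_width)

clean_trace <- function(model = control_model(), gain = 1, noise = 0,
                        seed = 1L, n_points = 50, baseline_bp = 110.5) {
  simulate_trace(model,
                 measurement_model(au_gain = gain, noise_sd_au = noise,
                                   seed = seed),
                 sweep_protocol(40, 190, baseline_bp, n_points))
}

# fit an exactly known cubic by sampling it noise-free over [40, 190]
curve_from_coefs <- function(coefs, n = 20, dom = c(40, 190)) {
  bp <- seq(dom[1], dom[2], length.out = n)
  y <- drop(outer(bp, 0:3, `^`) %*% coefs)
  fit_curve(flow_trace("synthcubic", "test", bp, pmax(y, 0)))
}

# cubic through four prescribed (bp, flow) points (Vandermonde solve)
cubic_through <- function(bps, flows) {
  stopifnot(length(bps) == 4, length(flows) == 4)
  solve(outer(bps, 0:3, `^`), flows)
}

# dense grid-scan oracle for threshold crossings of a calibrated curve:
# sign changes of (curve - threshold) on a 0.01 mmHg grid, refined by
# linear interpolation inside the bracketing step
grid_scan_limits <- function(curve, lo_thr, hi_thr, baseline_bp,
                             step = 0.01) {
  g <- seq(curve$fit_domain[1], curve$fit_domain[2], by = step)
  v <- predict(curve, g)
  crossings <- function(thr) {
    d <- v - thr
    i <- which(d[-1] * d[-length(d)] <= 0 & d[-1] != d[-length(d)])
    g[i] + step * d[i] / (d[i] - d[i + 1])
  }
  lo <- crossings(lo_thr); lo <- lo[lo < baseline_bp]
  hi <- crossings(hi_thr); hi <- hi[hi > baseline_bp]
  list(lower = if (length(lo)) max(lo) else NA_real_,
       upper = if (length(hi)) min(hi) else NA_real_)
}

# small paper-spread-like microsphere fixture with chosen cv
microsphere_fixture <- function(cv, seed, n = c(control = 6, sham = 6,
                                                SAH = 7)) {
  means <- c(control = 174.8, sham = 180.5, SAH = 116.9)
  weights <- c(cortex_ipsi = 120.8)
  do.call(rbind, lapply(names(means), function(g)
    simulate_microsphere_experiment(
      c(cortex_ipsi = unname(means[g])),
      measurement_model(microsphere_cv = cv, seed = seed + match(g, names(means))),
      n_animals = n[g], withdrawal_rate = 0.1,
      tissue_weights = weights, group = g)))
}
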