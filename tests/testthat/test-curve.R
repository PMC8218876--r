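test_that("cubic fit interpolates exact polynomial data", {
  # a pure line: coefficient vector (0, 2, 0, 0) to machine precision
  bp <- seq(40, 190, length.out = 12)
  cur <- fit_curve(flow_trace("a1", "g", bp, 2 * bp))
  expect_equal(cur$coefficients, c(0, 2, 0, 0), tolerance = 1e-8)
  expect_equal(cur$fit_domain, c(40, 190))
  # a known cubic, checked against brute-force normal equations
  coefs <- c(50, 1.2, -0.01, 3e-5)
  bp <- seq(45, 185, length.out = 15)
  y <- drop(outer(bp, 0:3, `^`) %*% coefs)
  cur <- fit_curve(flow_trace("a2", "g", bp, y))
  X <- outer(bp, 0:3, `^`)
  oracle <- drop(solve(t(X) %*% X, t(X) %*% y))
  expect_equal(cur$coefficients, coefs, tolerance = 1e-6)
  expect_equal(cur$coefficients, oracle, tolerance = 1e-6)
})

test_that("adding a constant to all flows shifts only the intercept", {
  tr <- clean_trace(noise = 0)
  c0 <- fit_curve(tr)
  tr2 <- flow_trace("a", "g", tr$map_mmHg, tr$cbf_au + 25)
  c1 <- fit_curve(tr2)
  expect_equal(c1$coefficients[1] - c0$coefficients[1], 25,
               tolerance = 1e-6)
  expect_equal(c1$coefficients[-1], c0$coefficients[-1], tolerance = 1e-6)
})

test_that("cubic beats any lower-degree polynomial in residual sum of squares", {
  tr <- clean_trace(noise = 8, seed = 21)
  rss3 <- fit_curve(tr, degree = 3)$rss
  for (d in 1:2) {
    X <- outer(tr$map_mmHg, 0:d, `^`)
    rss_d <- sum(stats::lm.fit(X, tr$cbf_au)$residuals^2)
    expect_lte(rss3, rss_d + 1e-8)
  }
})

test_that("fitting eligibility gates reject inadequate traces", {
  expect_error(flow_trace("a", "g", c(100, 110, 120), c(1, 1, 1)),
               "at least 8")
  # narrow pressure span
  bp <- seq(100, 140, length.out = 10)
  expect_error(fit_curve(flow_trace("a", "g", bp, bp)), "span")
  # too few distinct pressures
  bp <- rep(c(40, 90, 150), c(4, 4, 4))
  expect_error(fit_curve(flow_trace("a", "g", bp, bp)), "distinct")
})

test_that("calibration anchors the curve exactly at baseline", {
  tr <- clean_trace(gain = 3.7, noise = 4, seed = 13)
  cur <- fit_curve(tr)
  cal <- calibrate(cur, 174.8, 110.5)
  expect_identical(cal$unit, "absolute")
  expect_equal(predict(cal, 110.5), 174.8, tolerance = 1e-12)
  # identity and homogeneity of the calibration factor
  au_at_base <- predict(cur, 110.5)
  cal_id <- calibrate(cur, au_at_base, 110.5)
  expect_equal(cal_id$calibration_factor, 1)
  expect_equal(cal_id$coefficients, cur$coefficients)
  cal2 <- calibrate(cur, 2 * 174.8, 110.5)
  expect_equal(cal2$calibration_factor, 2 * cal$calibration_factor)
  expect_equal(cal2$coefficients, 2 * cal$coefficients)
})

test_that("calibration refuses bad anchors and double application", {
  tr <- clean_trace()
  cur <- fit_curve(tr)
  expect_error(calibrate(cur, 174.8, 20), "outside the fit domain")
  expect_error(calibrate(calibrate(cur, 174.8, 110.5), 174.8, 110.5),
               "already calibrated")
  # a curve that is non-positive at the anchor cannot be calibrated
  neg <- fit_curve(flow_trace("a", "g", seq(40, 190, length.out = 10),
                              rep(1, 10)))
  neg$coefficients <- c(-5, 0, 0, 0)  # force a non-positive anchor value
  expect_error(calibrate(neg, 100, 110), "not positive")
})

test_that("flow thresholds bracket baseline by the stated fraction", {
  expect_equal(compute_thresholds(100, 0.20),
               c(lower = 80, upper = 120))
  expect_equal(compute_thresholds(174.8, 0.20),
               c(lower = 139.84, upper = 209.76))
  expect_equal(unname(compute_thresholds(150, 0)), c(150, 150))
  expect_error(compute_thresholds(-1), "positive")
})

test_that("limits are the first threshold crossings away from baseline", {
  # cubic constructed through chosen crossings: 80% of baseline at 77.3,
  # 120% at 135.0, baseline flow at 110.5
  B <- 174.8
  coefs <- cubic_through(c(77.3, 110.5, 135.0, 40),
                         c(0.8 * B, B, 1.2 * B, 0.3 * B))
  cur <- curve_from_coefs(coefs)
  cal <- calibrate(cur, B, 110.5)
  lim <- find_limits(cal)
  expect_false(lim$lower_censored || lim$upper_censored)
  expect_equal(lim$lower_bp, 77.3, tolerance = 1e-6)
  expect_equal(lim$upper_bp, 135.0, tolerance = 1e-6)
  expect_equal(lim$range_width, 57.7, tolerance = 1e-6)
  # agreement with the dense grid-scan oracle
  oracle <- grid_scan_limits(cal, lim$lower_cbf_threshold,
                             lim$upper_cbf_threshold, 110.5)
  expect_equal(lim$lower_bp, oracle$lower, tolerance = 0.02)
  expect_equal(lim$upper_bp, oracle$upper, tolerance = 0.02)
})

test_that("a flat curve at baseline censors both limits", {
  bp <- seq(40, 190, length.out = 10)
  cur <- fit_curve(flow_trace("a", "g", bp, rep(50, 10)))
  cal <- calibrate(cur, 100, 110)
  lim <- find_limits(cal)
  expect_true(lim$lower_censored && lim$upper_censored)
  expect_equal(c(lim$lower_bp, lim$upper_bp), c(40, 190))  # domain edges
  expect_true(is.na(lim$range_width))
  expect_warning(r <- autoreg_range(lim), "censored")
  expect_true(is.na(r))
})

test_that("with two upper crossings the one nearest baseline is chosen", {
  # cubic that rises through 120% just above baseline, dips back, and
  # crosses again near the domain edge
  B <- 100
  coefs <- cubic_through(c(110, 125, 150, 185),
                         c(B, 1.2 * B, 1.1 * B, 1.35 * B))
  cur <- curve_from_coefs(coefs, n = 30, dom = c(100, 190))
  cal <- calibrate(cur, B, 110)
  lim <- find_limits(cal)
  oracle <- grid_scan_limits(cal, lim$lower_cbf_threshold,
                             lim$upper_cbf_threshold, 110)
  expect_false(lim$upper_censored)
  expect_equal(lim$upper_bp, oracle$upper, tolerance = 0.02)
  # the chosen crossing is the smallest one above baseline
  expect_lt(lim$upper_bp, 150)
})

test_that("find_limits demands a calibrated curve", {
  cur <- fit_curve(clean_trace())
  expect_error(find_limits(cur), "calibrated")
})

test_that("autoregulatory range arithmetic", {
  expect_equal(autoreg_range(77.3, 135.0), 57.7)
  expect_equal(autoreg_range(100, 100), 0)
})

test_that("percent change is signed relative to the reference", {
  expect_equal(percent_change(174.8, 116.9), 33.1, tolerance = 0.05)
  expect_equal(percent_change(123, 123), 0)
  expect_equal(percent_change(100, 200), -100)
  expect_error(percent_change(0, 100), "positive")
})

test_that("arbitrary-unit gain cancels: limits invariant under rescaling", {
  tr <- clean_trace(noise = 6, seed = 17)
  base <- NULL
  for (g in c(0.1, 1, 10)) {
    tg <- flow_trace("a", "g", tr$map_mmHg, g * tr$cbf_au)
    lim <- find_limits(calibrate(fit_curve(tg), 174.8, 110.5))
    if (is.null(base)) base <- lim
    expect_equal(lim$lower_bp, base$lower_bp, tolerance = 1e-9)
    expect_equal(lim$upper_bp, base$upper_bp, tolerance = 1e-9)
  }
})

test_that("widening the flow band never narrows the recovered range", {
  tr <- clean_trace(noise = 5, seed = 23)
  cal <- calibrate(fit_curve(tr), 174.8, 110.5)
  widths <- sapply(c(0.05, 0.10, 0.20, 0.30), function(f) {
    lim <- find_limits(cal, fraction = f)
    if (lim$lower_censored || lim$upper_censored) NA else lim$range_width
  })
  ok <- !is.na(widths)
  expect_true(all(diff(widths[ok]) >= -1e-9))
})
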