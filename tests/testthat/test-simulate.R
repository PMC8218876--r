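test_that("noise-free traces lie exactly on the gain-scaled true curve", {
  m <- control_model()
  for (gain in c(1, 2.5)) {
    tr <- clean_trace(m, gain = gain)
    expect_equal(tr$cbf_au, gain * evaluate_true_model(m, tr$map_mmHg),
                 tolerance = 1e-12)
  }
})

test_that("traces honor the protocol: count, span and ordering", {
  m <- control_model()
  p <- sweep_protocol(40, 190, 110.5, 50)
  tr <- simulate_trace(m, measurement_model(seed = 5), p)
  expect_equal(nrow(tr), 50)
  expect_equal(range(tr$map_mmHg), c(40, 190))
  # descending-then-ascending: pressures at or below baseline come first,
  # falling; the hypertensive tail rises
  below <- tr$map_mmHg[tr$map_mmHg <= 110.5]
  above <- tr$map_mmHg[tr$map_mmHg > 110.5]
  expect_true(all(diff(below) < 0))
  expect_true(all(diff(above) > 0))
  expect_true(all(tr$map_mmHg[seq_along(below)] <= 110.5))
  # random ordering permutes the same pressure multiset
  pr <- sweep_protocol(40, 190, 110.5, 50, ordering = "random")
  tr2 <- simulate_trace(m, measurement_model(seed = 5), pr)
  expect_equal(sort(tr2$map_mmHg), sort(tr$map_mmHg))
})

test_that("identical seeds reproduce identical traces, different seeds differ", {
  m <- control_model()
  p <- sweep_protocol(40, 190, 110.5, 50)
  a <- simulate_trace(m, measurement_model(noise_sd_au = 8, seed = 11), p)
  b <- simulate_trace(m, measurement_model(noise_sd_au = 8, seed = 11), p)
  c <- simulate_trace(m, measurement_model(noise_sd_au = 8, seed = 12), p)
  expect_identical(a$cbf_au, b$cbf_au)
  expect_false(identical(a$cbf_au, c$cbf_au))
})

test_that("trace simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(clean_trace(noise = 5, seed = 7))
  expect_identical(runif(1), before)
})

test_that("noise-free microsphere records invert the blood-flow equation", {
  rec <- simulate_microsphere_experiment(
    c(cortex_ipsi = 174.8), measurement_model(microsphere_cv = 0, seed = 1),
    n_animals = 4, withdrawal_rate = 0.1,
    tissue_weights = c(cortex_ipsi = 120.8))
  flows <- compute_blood_flow(rec)
  expect_equal(flows, rep(174.8, 4), tolerance = 1e-12)
  expect_equal(sd(flows), 0)
})

test_that("microsphere dispersion follows the requested CV and seed", {
  meas <- measurement_model(microsphere_cv = 0.2, seed = 31)
  rec <- simulate_microsphere_experiment(
    c(cortex_ipsi = 150), meas, n_animals = 500, withdrawal_rate = 0.1,
    tissue_weights = c(cortex_ipsi = 120))
  flows <- compute_blood_flow(rec)
  expect_equal(mean(flows), 150, tolerance = 0.05)  # mean-preserving
  expect_equal(sd(flows) / mean(flows), 0.2, tolerance = 0.15)
  rec2 <- simulate_microsphere_experiment(
    c(cortex_ipsi = 150), meas, n_animals = 500, withdrawal_rate = 0.1,
    tissue_weights = c(cortex_ipsi = 120))
  expect_identical(rec, rec2)
})

test_that("microsphere simulation rejects degenerate inputs", {
  meas <- measurement_model()
  expect_error(simulate_microsphere_experiment(
    numeric(0), meas, 3, 0.1, c(a = 100)), "at least one tissue")
  expect_error(simulate_microsphere_experiment(
    c(cortex_ipsi = 150), meas, 3, 0, c(cortex_ipsi = 100)), "positive")
  expect_error(simulate_microsphere_experiment(
    c(cortex_ipsi = 150), meas, 3, 0.1, c(other = 100)), "missing tissue")
})

test_that("the full study simulation is seed-deterministic", {
  d <- default_study_design(n_points = 20)
  a <- simulate_study(d)
  b <- simulate_study(d)
  expect_identical(a$traces, b$traces)
  expect_identical(a$microspheres, b$microspheres)
  d2 <- default_study_design(n_points = 20, seed = 999L)
  expect_false(identical(simulate_study(d2)$traces$cbf_au, a$traces$cbf_au))
})
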