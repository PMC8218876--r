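test_that("blood-flow equation matches hand arithmetic and its units", {
  # zero fluorescence -> zero flow
  expect_equal(compute_blood_flow(0, 500, 0.1, 120), 0)
  # unit ratio at 1 ml/min over 1 g of tissue -> 100 ml/100 g/min
  expect_equal(compute_blood_flow(7, 7, 1, 1000), 100)
  # tissue/reference ratio 2.112 at 0.1 ml/min over 120.8 mg
  expect_equal(compute_blood_flow(2.112, 1, 0.1, 120.8), 174.8,
               tolerance = 3e-4)
  # vectorised over a record table
  rec <- data.frame(fluor_tissue = c(0, 7), fluor_ref = c(500, 7),
                    withdrawal_rate_ml_min = c(0.1, 1),
                    tissue_weight_mg = c(120, 1000))
  expect_equal(compute_blood_flow(rec), c(0, 100))
})

test_that("blood flow is degree-1 homogeneous in signal and rate", {
  f0 <- compute_blood_flow(3.2, 1.5, 0.12, 95)
  expect_equal(compute_blood_flow(2 * 3.2, 1.5, 0.12, 95), 2 * f0)
  expect_equal(compute_blood_flow(3.2, 1.5, 2 * 0.12, 95), 2 * f0)
  expect_equal(compute_blood_flow(3.2, 2 * 1.5, 0.12, 95), f0 / 2)
  expect_equal(compute_blood_flow(3.2, 1.5, 0.12, 2 * 95), f0 / 2)
})

test_that("blood-flow equation rejects invalid records", {
  expect_error(compute_blood_flow(-1, 500, 0.1, 120), "non-negative")
  expect_error(compute_blood_flow(1, 0, 0.1, 120), "positive")
  expect_error(compute_blood_flow(1, 500, 0, 120), "positive")
  expect_error(compute_blood_flow(1, 500, 0.1, 0), "positive")
})

test_that("record validation drops bad rows with logged reasons", {
  rec <- data.frame(fluor_tissue = c(1, -1, 2), fluor_ref = c(5, 5, 0),
                    withdrawal_rate_ml_min = 0.1, tissue_weight_mg = 120)
  expect_message(out <- validate_microsphere_records(rec), "rejected 2/3")
  expect_equal(nrow(out), 1)
  rej <- attr(out, "rejected")
  expect_setequal(rej$row, c(2, 3))
  expect_true(any(grepl("fluor_tissue", rej$reason)))
  expect_true(any(grepl("fluor_ref", rej$reason)))
})

test_that("group summary computes mean and n-1 SEM", {
  expect_equal(summarize_group(c(100, 100, 100))$sem, 0)
  s <- summarize_group(c(90, 110), group = "control", tissue = "cortex_ipsi")
  expect_equal(s$mean, 100)
  expect_equal(s$sem, 10)  # SD 14.142 / sqrt(2)
  expect_equal(s$n, 2)
  # linearity under scaling
  s2 <- summarize_group(2 * c(90, 110))
  expect_equal(c(s2$mean, s2$sem), 2 * c(s$mean, s$sem))
  expect_error(summarize_group(100), "insufficient replicates")
})

test_that("no between-group variance gives F near zero and p near one", {
  vals <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)
  grp <- rep(c("a", "b", "c"), each = 3)
  cmp <- compare_groups(vals, grp)
  expect_equal(cmp$f_statistic, 0)
  expect_equal(cmp$anova_p, 1)
  expect_equal(nrow(cmp$pairwise), 3)  # all unordered pairs
  expect_true(all(cmp$pairwise$adjusted_p >= 0 & cmp$pairwise$adjusted_p <= 1))
})

test_that("two-group ANOVA F equals the squared two-sample t statistic", {
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(6, 100, 15)
    b <- rnorm(8, 120, 15)
    cmp <- compare_groups(c(a, b), rep(c("a", "b"), c(6, 8)))
    t2 <- t.test(a, b, var.equal = TRUE)$statistic^2
    expect_equal(cmp$f_statistic, unname(t2), tolerance = 1e-9)
  }
})

test_that("Tukey adjusted p matches a hand studentized-range computation", {
  set.seed(11)
  vals <- c(rnorm(6, 100, 10), rnorm(6, 115, 10), rnorm(7, 90, 10))
  grp <- rep(c("a", "b", "c"), c(6, 6, 7))
  cmp <- compare_groups(vals, grp)
  # Tukey-Kramer by hand: q = |diff| / sqrt((MSE/2) (1/n_i + 1/n_j))
  ns <- table(grp)
  means <- tapply(vals, grp, mean)
  mse <- sum(tapply(vals, grp, function(x) sum((x - mean(x))^2))) /
    (length(vals) - 3)
  for (r in seq_len(nrow(cmp$pairwise))) {
    i <- cmp$pairwise$group_a[r]; j <- cmp$pairwise$group_b[r]
    q <- abs(means[i] - means[j]) /
      sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    p_hand <- ptukey(q, nmeans = 3, df = length(vals) - 3,
                     lower.tail = FALSE)
    expect_equal(cmp$pairwise$adjusted_p[r], unname(p_hand),
                 tolerance = 1e-8)
  }
  # adjusted p is never below the unadjusted pairwise contrast p
  for (r in seq_len(nrow(cmp$pairwise))) {
    i <- cmp$pairwise$group_a[r]; j <- cmp$pairwise$group_b[r]
    tt <- abs(means[i] - means[j]) / sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    p_unadj <- 2 * pt(tt, df = length(vals) - 3, lower.tail = FALSE)
    expect_gte(cmp$pairwise$adjusted_p[r] + 1e-12, unname(p_unadj))
  }
})

test_that("group comparison enforces its preconditions", {
  expect_error(compare_groups(1:5, rep("a", 5)), "two groups")
  expect_error(compare_groups(1:5, c("a", "a", "a", "a", "b")), "n >= 2")
})

test_that("cv = 0 synthetic groups recover exact means and separate cleanly", {
  rec <- microsphere_fixture(cv = 0, seed = 1)
  flows <- data.frame(group = rec$group,
                      flow = compute_blood_flow(rec))
  means <- tapply(flows$flow, flows$group, mean)
  expect_equal(as.vector(means[c("control", "sham", "SAH")]),
               c(174.8, 180.5, 116.9), tolerance = 1e-12)
})
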