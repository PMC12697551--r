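test_that("residuals follow the lower/upper definitions with order preserved", {
  iv <- const_interval(0.05, 1, 3)
  res <- compute_residuals(iv, records_at(c(0.5, 3.4, 2)))
  expect_equal(res$lower_resid, c(0.5, -2.4, -1))
  expect_equal(res$upper_resid, c(-2.5, 0.4, -1))
  expect_equal(attr(res, "n_cal"), 3)

  # any in-band record has both residuals <= 0
  set.seed(8)
  inside <- records_at(runif(50, 1, 3))
  res2 <- compute_residuals(iv, inside)
  expect_true(all(res2$lower_resid <= 0 & res2$upper_resid <= 0))

  expect_error(compute_residuals(iv, records_at(numeric(0))),
               class = "refcal_empty_set")
})

test_that("conformal quantile equals a brute-force sort-and-index oracle", {
  oracle <- function(values, level) {
    k <- ceiling(level * (length(values) + 1))
    sort(values)[min(k, length(values))]
  }
  set.seed(99)
  for (n_cal in 1:50) {
    values <- rnorm(n_cal)
    for (level in c(0.5, 0.9, 0.95, 0.975, 0.99, 0.995)) {
      got <- conformal_quantile(values, level)
      expect_identical(got$value, oracle(values, level))
      expect_identical(got$overflow, ceiling(level * (n_cal + 1)) > n_cal)
    }
  }
})

test_that("conformal quantile handles the worked examples and ties", {
  expect_equal(conformal_quantile(1:9, 0.9)$value, 9)
  q <- conformal_quantile(c(0.5, -0.2, 1.3), 0.975)
  expect_equal(q$value, 1.3)
  expect_true(q$overflow)
  expect_equal(q$k, 4)
  # degenerate distribution: any level returns the common value
  for (level in c(0.5, 0.9, 0.99)) {
    expect_equal(conformal_quantile(rep(2.2, 7), level)$value, 2.2)
  }
  expect_error(conformal_quantile(numeric(0), 0.9),
               class = "refcal_empty_set")
})

test_that("calibration shifts both bounds by the conformal constants", {
  iv <- const_interval(0.05, 1, 3)
  set.seed(12)
  cal <- records_at(rnorm(100, 2, 1))
  res <- compute_residuals(iv, cal)
  expected_lo <- conformal_quantile(res$lower_resid, 1 - 0.05 / 2)$value
  expected_hi <- conformal_quantile(res$upper_resid, 1 - 0.05 / 2)$value
  civ <- suppressWarnings(reform_calibrate(iv, cal))
  expect_equal(civ$constants$c_lower, expected_lo)
  expect_equal(civ$constants$c_upper, expected_hi)
  b <- interval_bounds(civ, c(30, 70), "F")
  expect_equal(b$lower, rep(1 - expected_lo, 2))
  expect_equal(b$upper, rep(3 + expected_hi, 2))
  expect_true(civ$calibrated)

  # full_alpha convention uses the 1 - alpha level instead
  civ2 <- suppressWarnings(reform_calibrate(iv, cal, tail_level = "full_alpha"))
  expect_equal(civ2$constants$c_lower,
               conformal_quantile(res$lower_resid, 1 - 0.05)$value)
})

test_that("zero conformal constants leave the interval unchanged", {
  iv <- const_interval(0.5, 1, 3)
  # maxima of both residual sets are exactly 0 (values on the bounds)
  cal <- records_at(c(1, 2, 3))
  civ <- reform_calibrate(iv, cal)
  expect_equal(civ$constants$c_lower, 0)
  expect_equal(civ$constants$c_upper, 0)
  b0 <- interval_bounds(iv, 50, "F")
  b1 <- interval_bounds(civ, 50, "F")
  expect_equal(b1$lower, b0$lower)
  expect_equal(b1$upper, b0$upper)
})

test_that("constants are invariant to a common shift of data and bounds", {
  set.seed(13)
  values <- rnorm(60, 2, 1.5)
  shift <- 0.73
  iv <- const_interval(0.1, 1, 3)
  iv_shifted <- const_interval(0.1, 1 + shift, 3 + shift)
  c1 <- suppressWarnings(reform_calibrate(iv, records_at(values)))$constants
  c2 <- suppressWarnings(
    reform_calibrate(iv_shifted, records_at(values + shift))
  )$constants
  expect_equal(c1$c_lower, c2$c_lower)
  expect_equal(c1$c_upper, c2$c_upper)
})

test_that("constants grow with the level and never shrink the band", {
  set.seed(14)
  values <- rnorm(80)
  levels <- c(0.5, 0.9, 0.95, 0.99)
  cs <- vapply(levels, function(l) conformal_quantile(values, l)$value,
               numeric(1))
  expect_true(all(diff(cs) >= 0))
})

test_that("overflowed tails fall back to the extreme residual or infinity", {
  iv <- const_interval(0.01, 1, 3) # 99% interval
  cal <- records_at(rnorm(20, 2, 0.5)) # k = ceiling(0.995*21) = 21 > 20
  civ <- suppressWarnings(reform_calibrate(iv, cal))
  expect_equal(civ$constants$overflow_events, 2)
  res <- compute_residuals(iv, cal)
  expect_equal(civ$constants$c_lower, max(res$lower_resid))

  civ_inf <- suppressWarnings(reform_calibrate(iv, cal, overflow = "infinite"))
  expect_equal(civ_inf$constants$c_lower, Inf)
  fpr <- false_positive_rate(civ_inf, records_at(rnorm(100, 2, 5)))
  expect_equal(fpr$fpr_total, 0) # unbounded interval misses nothing
})

test_that("membership uses closed bounds and handles crossed intervals", {
  iv <- const_interval(0.05, 1, 3)
  m <- evaluate_membership(iv, records_at(c(2, 1, 3, 0.2, 3.8)))$membership
  expect_equal(as.character(m), c("inside", "below", "above", "below", "above"))

  crossed <- const_interval(0.05, 3, 1) # lower > upper everywhere
  mc <- evaluate_membership(crossed, records_at(c(2, 0.5, 3.5, 1.4)))$membership
  expect_false(any(mc == "inside"))
  expect_equal(as.character(mc[2]), "below") # only the lower bound is violated
  expect_equal(as.character(mc[3]), "above") # only the upper bound is violated
  expect_equal(as.character(mc[4]), "above") # both violated; upper (1) nearer
})

test_that("across-trial per-tail miscoverage respects the conformal bounds", {
  # calibration and validation exchangeable from a fixed shifted generator;
  # the naive interval is deliberately misspecified
  alpha <- 0.1
  iv <- const_interval(alpha, qnorm(alpha / 2), qnorm(1 - alpha / 2))
  n_trials <- 250
  for (n_cal in c(40, 120, 400)) {
    miss_lo <- miss_hi <- numeric(n_trials)
    for (t in seq_len(n_trials)) {
      set.seed(20000 + 7 * t + n_cal)
      cal <- records_at(rnorm(n_cal, 0.4, 1.3))
      val <- records_at(rnorm(500, 0.4, 1.3))
      civ <- suppressWarnings(reform_calibrate(iv, cal))
      fpr <- false_positive_rate(civ, val)
      miss_lo[t] <- fpr$fpr_lower
      miss_hi[t] <- fpr$fpr_upper
    }
    for (m in list(miss_lo, miss_hi)) {
      se <- sd(m) / sqrt(n_trials)
      expect_lte(mean(m), alpha / 2 + 1 / (n_cal + 1) + 3 * se)
      expect_gte(mean(m), alpha / 2 - 3 * se)
    }
  }
})

test_that("calibration depends on the interval only through its bounds", {
  d <- sim_bct_linear(400, seed = 55)
  fit <- fit_lss(d, lss_control(min_n = 50))
  iv <- naive_interval(fit, 0.05)
  set.seed(56)
  cal <- sim_bct_linear(150, seed = 57)

  path <- withr::local_tempfile(fileext = ".csv")
  write_gridded_interval(iv, path,
                         age_grid = seq(min(d$age), max(d$age),
                                        length.out = 401))
  iv_grid <- interpolate_interval(read_gridded_interval(path), margin = 1)
  c_direct <- suppressWarnings(reform_calibrate(iv, cal))$constants
  c_grid <- suppressWarnings(reform_calibrate(iv_grid, cal))$constants
  # bounds agree up to piecewise-linear interpolation error on a fine grid
  expect_equal(c_grid$c_lower, c_direct$c_lower, tolerance = 1e-4)
  expect_equal(c_grid$c_upper, c_direct$c_upper, tolerance = 1e-4)
})

test_that("residual diagnostics summarise both tails conservatively", {
  iv <- const_interval(0.05, 1, 3)
  res <- compute_residuals(iv, records_at(c(2, 2, 2)))
  # values at the interval centre: residuals all -1, none positive
  diag <- residual_diagnostics(res, bins = 5)
  expect_equal(diag$summary$frac_positive, c(0, 0))
  expect_equal(diag$summary$sd, c(0, 0))
  expect_true(all(tapply(diag$bins$count, diag$bins$tail, sum) == 3))

  res2 <- structure(
    tibble::tibble(lower_resid = c(-1, 1), upper_resid = c(-1, 1)),
    class = c("residual_set", class(tibble::tibble())),
    alpha = 0.05, n_cal = 2L
  )
  expect_equal(residual_diagnostics(res2)$summary$mean, c(0, 0))
})
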