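test_that("two-voltage Pion matches direct evaluation and its identities", {
  # equal readings mean no recombination
  expect_identical(compute_pion_two_voltage(2.000, 2.000), 1)
  # direct evaluation: (1 - 2) / (1.010 - 2)
  expect_equal(compute_pion_two_voltage(1.010, 1.000), 1 / 0.99,
               tolerance = 1e-12)
  # invariant under common rescaling of the readings
  expect_equal(compute_pion_two_voltage(1.2e-8 * 1.010, 1.2e-8 * 1.000),
               compute_pion_two_voltage(1.010, 1.000), tolerance = 1e-12)
  # vectorized
  expect_length(compute_pion_two_voltage(c(1.01, 1.02), c(1, 1)), 2L)
})

test_that("two-voltage formula is exactly inverted over the physical range", {
  for (p in seq(1.0, 1.05, by = 0.005)) {
    for (vr in c(1.5, 2, 3, 4)) {
      mr <- vr + (1 - vr) / p
      expect_equal(compute_pion_two_voltage(mr, 1, v_high = vr * 150,
                                            v_low = 150),
                   p, tolerance = 1e-12)
    }
  }
})

test_that("two-voltage computation rejects non-physical inputs", {
  # reading ratio at the voltage ratio: zero denominator
  expect_error(compute_pion_two_voltage(2.0, 1.0), "saturation|swapped")
  expect_error(compute_pion_two_voltage(2.5, 1.0), "saturation|swapped")
  expect_error(compute_pion_two_voltage(-1, 1), "positive")
  expect_error(compute_pion_two_voltage(1, 0), "positive")
  expect_error(compute_pion_two_voltage(1, 1, v_high = 150, v_low = 300),
               "v_high > v_low")
})

test_that("renormalization fixes 100 at the reference and is scale-free", {
  sc <- reference_scale(4.8e-9, "10FFF")
  expect_identical(renormalize_signal(4.8e-9, sc), 100)
  expect_identical(renormalize_signal(2.4e-9, sc), 50)
  expect_identical(renormalize_signal(0, sc), 0)
  # multiplying reading and reference by any k > 0 changes nothing
  expect_equal(renormalize_signal(1.2, reference_scale(2.4)),
               renormalize_signal(1.2e8, reference_scale(2.4e8)))
  expect_error(reference_scale(0), "positive")
  expect_error(renormalize_signal(-1, sc), "non-negative")
})

test_that("calibration evaluation is linear with the intercept at zero signal", {
  cal <- cal_10fff()
  expect_identical(pion_at_signal(0, cal), 0.9992)
  expect_equal(pion_at_signal(100, cal), 1.0175, tolerance = 1e-12)
  expect_equal(pion_at_signal(70.8, cal), 1.0121564, tolerance = 1e-12)
  for (c2 in all_cals()) expect_identical(pion_at_signal(0, c2), c2$intercept_b)
  expect_error(pion_at_signal(-1, cal), "non-negative")
  expect_warning(pion_at_signal(150, cal), "beyond")
  expect_silent(pion_at_signal(119, cal))
})

test_that("signal correction and its inverse are an exact round trip", {
  expect_equal(correct_signal(100, cal_10fff()), 101.75, tolerance = 1e-12)
  expect_equal(correct_signal(63.4, cal_6fff()), 63.8520852, tolerance = 1e-6)
  expect_identical(correct_signal(0, cal_10fff()), 0)
  expect_identical(uncorrect_signal(0, cal_10fff()), 0)
  expect_equal(uncorrect_signal(101.75, cal_10fff()), 100, tolerance = 1e-9)
  s_grid <- seq(0, 120, by = 0.5)
  for (cal in all_cals()) {
    expect_equal(uncorrect_signal(correct_signal(s_grid, cal), cal), s_grid,
                 tolerance = 1e-9)
    # corrected signal is strictly increasing on the evaluation window
    expect_true(all(diff(correct_signal(s_grid, cal)) > 0))
  }
  # slope-zero degenerate branch: S* = S / b
  expect_equal(uncorrect_signal(5, cal_zero()), 5)
})

test_that("signal inversion agrees with a bisection root-finding oracle", {
  cal <- cal_10fff()
  for (s in c(0.5, 10, 63.4, 100, 118)) {
    target <- correct_signal(s, cal)
    oracle <- bisect_root(
      function(x) cal$slope_m * x^2 + cal$intercept_b * x - target, 0, 130)
    expect_equal(uncorrect_signal(target, cal), oracle, tolerance = 1e-9)
  }
})

test_that("noiseless calibration fits are recovered exactly", {
  s <- seq(10, 110, length.out = 10)
  cal <- fit_pion_calibration(s, 1.5e-4 * s + 1.000, "exact", n_boot = 200,
                              seed = 3)
  expect_equal(cal$slope_m, 1.5e-4, tolerance = 1e-12)
  expect_equal(cal$intercept_b, 1.000, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_identical(cal$fitted_support, range(s))
  expect_identical(cal$n_points, 10L)
})

test_that("calibration fitting rejects underdetermined input", {
  expect_error(fit_pion_calibration(c(1, 2), c(1, 1.001), "x"), "3 points")
  expect_error(fit_pion_calibration(rep(50, 5), rep(1.01, 5), "x"),
               "degenerate")
  expect_error(fit_pion_calibration(1:5, 1:4, "x"), "same length")
})

test_that("bootstrap intervals are reproducible and cover a noisy slope", {
  gen <- cal_10fff()
  set.seed(42)
  s <- runif(60, 5, 110)
  p <- gen$slope_m * s + gen$intercept_b + rnorm(60, 0, 0.002)
  fit1 <- fit_pion_calibration(s, p, "10FFF", n_boot = 500, seed = 11)
  fit2 <- fit_pion_calibration(s, p, "10FFF", n_boot = 500, seed = 11)
  expect_identical(fit1$slope_interval, fit2$slope_interval)
  expect_gt(gen$slope_m, fit1$slope_interval[1])
  expect_lt(gen$slope_m, fit1$slope_interval[2])
})

test_that("bootstrap slope intervals cover the generating slope ~95% of the time", {
  gen <- cal_10fff()
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    s <- runif(60, 5, 110)
    p <- gen$slope_m * s + gen$intercept_b + rnorm(60, 0, 0.002)
    fit <- fit_pion_calibration(s, p, "10FFF", n_boot = 400, seed = r)
    if (fit$slope_interval[1] <= gen$slope_m &&
        gen$slope_m <= fit$slope_interval[2]) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("MU-rate slope test flags only real trends", {
  null_data <- generate_mu_rate_set(seed = 7)
  res <- mu_rate_slope_test(null_data$mu_rate, null_data$pion,
                            n_boot = 1000, seed = 7)
  expect_true(res$contains_zero)
  expect_lt(res$interval[1], res$slope)
  expect_gt(res$interval[2], res$slope)
  # strong deterministic trend: zero cannot be credible
  mu <- rep(c(400, 800, 1200, 1600, 2400), each = 3)
  res2 <- mu_rate_slope_test(mu, 1.000 + 5e-5 * mu, n_boot = 500, seed = 1)
  expect_false(res2$contains_zero)
  expect_equal(res2$slope, 5e-5, tolerance = 1e-10)
  expect_error(mu_rate_slope_test(rep(400, 5), rnorm(5, 1.01, 1e-4)),
               "distinct")
})

test_that("calibration objects enforce their invariants", {
  expect_error(pion_calibration("x", 1e-4, 1.2), "0.95")
  expect_error(pion_calibration("x", 1e-4, 1, slope_interval = c(2e-4, 3e-4)),
               "contain")
  expect_error(pion_calibration("x", NaN, 1), "finite")
  cal <- pion_calibration("x", 1e-4, 1, r_squared = 0.5)
  expect_s3_class(cal, "pion_calibration")
  expect_output(print(cal), "Pion")
})
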