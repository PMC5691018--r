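test_that("depth-dose correction reproduces the published 10 cm values", {
  pair6 <- correct_pdd(pdd_two_point(63.4), cal_6fff())
  expect_equal(round(dose_function_at(pair6$corrected, 10), 1), 63.2)
  expect_equal(dose_function_at(pair6$uncorrected, 10), 63.4)
  # higher-energy beam: the Pion ratio lowers 70.8 by ~0.4 units
  pair10 <- correct_pdd(pdd_two_point(70.8), cal_10fff())
  expect_equal(dose_function_at(pair10$corrected, 10), 70.42818,
               tolerance = 1e-6)
})

test_that("all scan corrections are the identity for a zero-slope calibration", {
  curve <- pdd_two_point(63.4)
  pair <- correct_pdd(curve, cal_zero())
  expect_equal(pair$corrected$values, pair$uncorrected$values)
  sad_curve <- scan_curve("depth", c(2.4, 10, 20), c(100, 70, 57.2),
                          geometry = "SAD")
  pair_tmr <- correct_tmr(sad_curve, cal_zero())
  expect_equal(pair_tmr$corrected$values, pair_tmr$uncorrected$values)
  prof <- scan_curve("crossplane", seq(-6, 6, 0.2),
                     100 * exp(-(seq(-6, 6, 0.2) / 4)^4),
                     geometry = "SSD", depth_of_curve = 2.4)
  pair_oar <- correct_oar(prof, cal_zero())
  expect_equal(pair_oar$corrected$values, pair_oar$uncorrected$values)
  pair_rdf <- correct_rdf(c(4, 10, 20), c(92, 100, 106), cal_zero())
  expect_equal(pair_rdf$corrected$values, pair_rdf$uncorrected$values)
  expect_identical(width_delta(prof, cal_zero())$delta_w, 0)
})

test_that("corrected depth dose never exceeds the uncorrected beyond dmax", {
  model <- beam_preset("10fff")
  for (cal in list(cal_10fff(), cal_6fff())) {
    curve <- generate_pdd(model, cal, seed = 5)$curve
    pair <- correct_pdd(curve, cal)
    beyond <- curve$positions > model$dmax
    expect_true(all(pair$corrected$values[beyond] <=
                    pair$uncorrected$values[beyond] + 1e-12))
  }
})

test_that("depth-dose correction validates its inputs", {
  expect_error(correct_pdd(pdd_two_point(63.4, geometry = "SAD"),
                           cal_6fff()), "SSD")
  expect_error(correct_pdd(pdd_two_point(63.4, energy = "10FFF"),
                           cal_6fff()), "does not match")
  prof <- scan_curve("crossplane", -2:2, c(50, 99, 100, 99, 50),
                     depth_of_curve = 2.4)
  expect_error(correct_pdd(prof, cal_6fff()), "depth scan")
})

test_that("TMR correction applies the Pion ratio at fixed isocenter", {
  curve <- scan_curve("depth", c(2.4, 20), c(100, 57.2), geometry = "SAD")
  pair <- correct_tmr(curve, cal_10fff())
  expect_equal(dose_function_at(pair$corrected, 20), 0.5675969,
               tolerance = 1e-6)
  expect_equal(dose_function_at(pair$uncorrected, 20), 0.572)
  # self-ratio at dmax
  expect_equal(dose_function_at(pair$corrected, 2.4), 1)
  expect_error(correct_tmr(pdd_two_point(63.4), cal_6fff()), "SAD")
})

test_that("OAR correction cancels on flat profiles and lowers shoulders", {
  x <- seq(-6, 6, 0.25)
  flat <- scan_curve("crossplane", x, rep(80, length(x)),
                     depth_of_curve = 2.4)
  pair <- correct_oar(flat, cal_10fff())
  expect_equal(pair$corrected$values, rep(100, length(x)))
  # off-axis signals below the CAX signal get a Pion ratio < 1
  sig <- 90 * exp(-(x / 5)^2)
  prof <- scan_curve("crossplane", x, sig, depth_of_curve = 2.4)
  pair2 <- correct_oar(prof, cal_10fff())
  off <- x != 0
  expect_true(all(pair2$corrected$values[off] <
                  pair2$uncorrected$values[off]))
  shifted <- scan_curve("crossplane", x + 10, sig, depth_of_curve = 2.4)
  expect_error(correct_oar(shifted, cal_10fff()), "outside the scanned range")
})

test_that("OAR correction is largest at dmax and fades with depth", {
  model <- beam_preset("10fff")
  cal <- cal_10fff()
  max_delta <- function(depth) {
    curve <- generate_profile(model, cal, field_size = 4, depth = depth,
                              seed = 2)$curve
    pair <- correct_oar(curve, cal)
    max(abs(difference_curves(pair$corrected, pair$uncorrected)$delta_abs))
  }
  expect_gte(max_delta(model$dmax), max_delta(35))
})

test_that("RDF corrections are of order 1e-3 near the reference signal", {
  fs <- c(3, 4, 6, 10, 20)
  s <- c(90, 93, 96, 100, 110)
  pair <- correct_rdf(fs, s, cal_10fff())
  d <- abs(pair$corrected$values - pair$uncorrected$values)
  expect_true(all(d < 5e-3))
  expect_true(max(d) > 1e-4)
  # the reference field itself is exactly 1 in both curves
  expect_equal(pair$corrected$values[fs == 10], 1)
  expect_equal(pair$uncorrected$values[fs == 10], 1)
  expect_error(correct_rdf(c(4, 6), c(92, 96), cal_10fff()),
               "reference field")
})

test_that("difference curves carry the published sign and structure", {
  a <- dose_function_curve(10, 63.2, "pdd", corrected = TRUE)
  b <- dose_function_curve(10, 63.4, "pdd")
  d <- difference_curves(a, b)
  expect_equal(d$delta_abs, -0.2, tolerance = 1e-12)
  same <- difference_curves(b, b)
  expect_true(all(same$delta_abs == 0))
  expect_true(all(same$delta_rel == 0))
  expect_error(difference_curves(a, dose_function_curve(11, 63.4, "pdd")),
               "grid")
  expect_error(difference_curves(a, dose_function_curve(10, 0.63, "tmr")),
               "kind")
})

test_that("synthetic depth-dose differences vanish at dmax with an interior extremum", {
  model <- beam_preset("10fff")
  cal <- cal_10fff()
  curve <- generate_pdd(model, cal, seed = 3)$curve
  pair <- correct_pdd(curve, cal)
  d <- difference_curves(pair$corrected, pair$uncorrected)
  i_dmax <- which.max(curve$signals)
  expect_lt(abs(d$delta_abs[i_dmax]), 1e-9)
  # beyond dmax, |delta_abs| peaks at an intermediate depth: small near
  # dmax (Pion ratio ~ 1) and small again at depth (signal ~ 0)
  beyond <- d$positions >= model$dmax
  da <- abs(d$delta_abs[beyond])
  i_peak <- which.max(da)
  expect_gt(i_peak, 1L)
  expect_lt(i_peak, length(da))
  # relative difference grows monotonically beyond dmax
  expect_true(all(diff(abs(d$delta_rel[beyond])) >= -1e-9))
})

test_that("50% field edges are found by outward interpolation", {
  # symmetric trapezoid: flat 100 inside |x|<2, ramp to 0 at |x|=3
  x <- seq(-4, 4, by = 0.5)
  v <- pmin(100, pmax(0, 100 * (3 - abs(x))))
  w <- field_width_50(dose_function_curve(x, v, "oar"))
  expect_equal(w$left, -2.5, tolerance = 1e-12)
  expect_equal(w$right, 2.5, tolerance = 1e-12)
  expect_equal(w$width, 5, tolerance = 1e-12)
  # translation moves the crossings, not the width
  v_shift <- pmin(100, pmax(0, 100 * (3 - abs(x - 0.4))))
  w2 <- field_width_50(dose_function_curve(x, v_shift, "oar"))
  expect_equal(w2$left, -2.1, tolerance = 1e-12)
  expect_equal(w2$right, 2.9, tolerance = 1e-12)
  expect_equal(w2$width, 5, tolerance = 1e-12)
  expect_error(field_width_50(dose_function_curve(x, rep(100, length(x)),
                                                  "oar")),
               "never crosses")
})

test_that("field width agrees with a brute-force fine-grid oracle", {
  x <- seq(-5, 5, by = 0.2)
  edge <- 2.6
  v <- 100 * (1 - 0.01 * abs(x)) * pnorm((edge - abs(x)) / 0.35) /
    pnorm(edge / 0.35)
  prof <- dose_function_curve(x, v, "oar")
  w <- field_width_50(prof)
  # oracle: scan the interpolated profile on a 1000x finer grid for the
  # first sample below 50 moving outward
  fine <- seq(0, 5, by = 0.2 / 1000)
  vf <- approx(x, v, xout = fine)$y
  right_oracle <- fine[which(vf < 50)[1]]
  expect_lt(abs(w$right - right_oracle), 0.2 / 1000 + 1e-12)
  expect_lt(abs(-w$left - right_oracle), 0.2 / 1000 + 1e-12)
})

test_that("the correction narrows the field by well under a millimetre", {
  model <- beam_preset("10fff")
  cal <- cal_10fff()
  prof_dmax <- generate_profile(model, cal, field_size = 4,
                                depth = model$dmax, seed = 4)$curve
  wr <- width_delta(prof_dmax, cal)
  expect_lt(wr$delta_w, 0)
  expect_lt(abs(wr$delta_w), 0.02)
  prof_deep <- generate_profile(model, cal, field_size = 4, depth = 35,
                                seed = 4)$curve
  wr_deep <- width_delta(prof_deep, cal)
  expect_lte(abs(wr_deep$delta_w), abs(wr$delta_w))
  expect_output(print(wr), "delta_w")
})
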