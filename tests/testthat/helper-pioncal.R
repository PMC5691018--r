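# Shared fixtures, built in code.

# published-style calibrations used throughout: a steep high-energy FFF
# slope, a shallower low-energy FFF slope, and a pooled flattened-beam
# group
cal_10fff <- function() {
  pion_calibration("10FFF", 1.83e-4, 0.9992,
                   slope_interval = c(1.43e-4, 2.23e-4),
                   intercept_interval = c(0.996, 1.003),
                   r_squared = 0.931)
}
cal_6fff <- function() {
  pion_calibration("6FFF", 9.67e-5, 1.0010,
                   slope_interval = c(6.54e-5, 1.28e-4),
                   intercept_interval = c(0.999, 1.003),
                   r_squared = 0.706)
}
cal_mv <- function() {
  pion_calibration("6/10MV", 5.15e-5, 0.9999,
                   slope_interval = c(-1.08e-4, 2.10e-4),
                   intercept_interval = c(0.984, 1.016),
                   r_squared = 0.693)
}
cal_zero <- function() pion_calibration("flat", 0, 1)

all_cals <- function() list(cal_10fff(), cal_6fff(), cal_mv())

# independent root-finding oracle for the signal-inversion quadratic
bisect_root <- function(f, lo, hi, tol = 1e-12) {
  flo <- f(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# minimal two-point depth scan holding a dmax sample and a 10 cm sample
pdd_two_point <- function(s10, energy = "", geometry = "SSD") {
  scan_curve("depth", c(2.4, 10), c(100, s10), energy_label = energy,
             geometry = geometry)
}
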