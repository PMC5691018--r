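# Two-voltage ion recombination measurement and the linear Pion(signal)
# calibration that lets single-voltage scan data be corrected afterwards.

#' Ion collection efficiency from a two-voltage measurement
#'
#' Computes the ion recombination correction Pion from a pair of raw
#' electrometer readings taken at a high and a low chamber bias voltage
#' (Boag's two-voltage technique),
#' \deqn{P_{ion} = \frac{1 - V_h/V_l}{M^*_h/M^*_l - V_h/V_l}.}
#' The result depends only on the ratios \eqn{V_h/V_l} and
#' \eqn{M^*_h/M^*_l}, so it is invariant under a common rescaling of the
#' two readings (electrometer sensitivity cancels).
#'
#' @param m_high,m_low Raw electrometer readings at the high and low
#'   voltage, in any common charge unit; both must be positive.
#' @param v_high,v_low Bias voltages in volts with `v_high > v_low > 0`.
#'   Defaults are the conventional 300 V / 150 V pair.
#' @return Numeric vector of Pion values (dimensionless, >= 1 when
#'   `m_high <= m_low`, exactly 1 when the readings are equal).
#' @examples
#' compute_pion_two_voltage(m_high = 1.010, m_low = 1.000)
#' compute_pion_two_voltage(2, 2) # no recombination
#' @export
compute_pion_two_voltage <- function(m_high, m_low, v_high = 300, v_low = 150) {
  if (any(!is.finite(v_high)) || any(!is.finite(v_low)) ||
      any(v_low <= 0) || any(v_high <= v_low)) {
    stop("voltages must satisfy v_high > v_low > 0", call. = FALSE)
  }
  if (any(!is.finite(m_high)) || any(!is.finite(m_low)) ||
      any(m_high <= 0) || any(m_low <= 0)) {
    stop("electrometer readings must be positive and finite", call. = FALSE)
  }
  vr <- v_high / v_low
  mr <- m_high / m_low
  if (any(mr >= vr)) {
    stop("reading ratio m_high/m_low must be below v_high/v_low; ",
         "check for saturation or swapped inputs", call. = FALSE)
  }
  (1 - vr) / (mr - vr)
}

#' Reference scale for signal renormalization
#'
#' The renormalization convention assigns 100 units to the uncorrected
#' reading for a 10x10 cm^2 field with the chamber at isocenter (SAD
#' setup) at the depth of dose maximum, taken at the high voltage. All
#' other readings for the same beam energy are expressed relative to
#' that reading, including readings taken at the low voltage.
#'
#' @param reference_reading Raw electrometer reading for the reference
#'   field at the high voltage (any charge unit, > 0).
#' @param energy_label Beam-energy group name, e.g. `"10FFF"`.
#' @return An object of class `reference_scale`.
#' @seealso [renormalize_signal()]
#' @export
reference_scale <- function(reference_reading, energy_label = "") {
  if (!is.numeric(reference_reading) || length(reference_reading) != 1L ||
      !is.finite(reference_reading) || reference_reading <= 0) {
    stop("reference_reading must be a single positive number", call. = FALSE)
  }
  structure(
    list(reference_reading = as.numeric(reference_reading),
         energy_label = as.character(energy_label)),
    class = "reference_scale"
  )
}

#' @export
print.reference_scale <- function(x, ...) {
  cat(sprintf("<reference_scale> %s: 100 units = reading %g\n",
              if (nzchar(x$energy_label)) x$energy_label else "(unlabelled)",
              x$reference_reading))
  invisible(x)
}

#' Renormalize a raw reading to the 100-unit reference scale
#'
#' Converts a raw electrometer reading to reference units,
#' \eqn{S^* = 100\, M^* / M^*_{ref}}. The result is invariant under a
#' common rescaling of reading and reference.
#'
#' @param m_star Raw uncorrected reading(s), >= 0.
#' @param scale A [reference_scale()] object, or a single positive number
#'   taken as the reference reading.
#' @return Renormalized signal(s) `s_star` in reference units.
#' @export
renormalize_signal <- function(m_star, scale) {
  ref <- if (inherits(scale, "reference_scale")) scale$reference_reading else scale
  if (!is.numeric(ref) || length(ref) != 1L || !is.finite(ref) || ref <= 0) {
    stop("reference reading must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(m_star)) || any(m_star < 0)) {
    stop("m_star must be finite and non-negative", call. = FALSE)
  }
  100 * (m_star / ref)
}

#' Linear Pion calibration for one beam-energy group
#'
#' Container for the fitted linear relation `Pion = slope_m * s_star +
#' intercept_b` between the collection-efficiency correction and the
#' renormalized uncorrected signal, together with 95% interval estimates
#' and fit diagnostics. Usually produced by [fit_pion_calibration()] or
#' read from JSON with [read_calibration_json()]; construct directly to
#' encode externally published parameters.
#'
#' @param energy_label Beam-energy group name (e.g. `"10FFF"`, `"6FFF"`,
#'   `"6/10MV"`). Corrections check this label against scan curves.
#' @param slope_m Pion change per reference unit (1/unit).
#' @param intercept_b Pion at zero signal (dimensionless); physically
#'   expected near 1, constrained to `[0.95, 1.05]`.
#' @param slope_interval,intercept_interval Optional 95% interval
#'   estimates (length-2 numeric, must contain the point estimate).
#' @param r_squared Coefficient of determination in `[0, 1]`, or `NA`.
#' @param fitted_support Range of `s_star` used in the fit (length-2).
#' @param v_high,v_low Voltages used for the underlying two-voltage
#'   measurements (metadata only).
#' @param n_points,seed Fit metadata carried for reproducibility.
#' @return An object of class `pion_calibration`.
#' @export
pion_calibration <- function(energy_label, slope_m, intercept_b,
                             slope_interval = NULL, intercept_interval = NULL,
                             r_squared = NA_real_,
                             fitted_support = c(0, 120),
                             v_high = 300, v_low = 150,
                             n_points = NA_integer_, seed = NA_integer_) {
  stopifnot(is.character(energy_label), length(energy_label) == 1L)
  if (!is.numeric(slope_m) || length(slope_m) != 1L || !is.finite(slope_m)) {
    stop("slope_m must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(intercept_b) || length(intercept_b) != 1L ||
      !is.finite(intercept_b)) {
    stop("intercept_b must be a single finite number", call. = FALSE)
  }
  if (intercept_b < 0.95 || intercept_b > 1.05) {
    stop("intercept_b outside the physically sane range [0.95, 1.05]",
         call. = FALSE)
  }
  check_interval <- function(iv, est, what) {
    if (is.null(iv)) return(NULL)
    if (!is.numeric(iv) || length(iv) != 2L || any(!is.finite(iv)) ||
        iv[1] > iv[2]) {
      stop(what, " must be an increasing length-2 numeric", call. = FALSE)
    }
    if (est < iv[1] || est > iv[2]) {
      stop(what, " must contain its point estimate", call. = FALSE)
    }
    as.numeric(iv)
  }
  slope_interval <- check_interval(slope_interval, slope_m, "slope_interval")
  intercept_interval <- check_interval(intercept_interval, intercept_b,
                                       "intercept_interval")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(fitted_support) || length(fitted_support) != 2L ||
      any(!is.finite(fitted_support)) ||
      fitted_support[1] > fitted_support[2]) {
    stop("fitted_support must be an increasing length-2 numeric", call. = FALSE)
  }
  structure(
    list(energy_label = energy_label,
         slope_m = as.numeric(slope_m),
         intercept_b = as.numeric(intercept_b),
         slope_interval = slope_interval,
         intercept_interval = intercept_interval,
         r_squared = as.numeric(r_squared),
         fitted_support = as.numeric(fitted_support),
         v_high = as.numeric(v_high), v_low = as.numeric(v_low),
         n_points = n_points, seed = seed),
    class = "pion_calibration"
  )
}

#' @export
print.pion_calibration <- function(x, ...) {
  cat(sprintf("<pion_calibration> %s\n", x$energy_label))
  cat(sprintf("  Pion = %.4g * S* + %.5g\n", x$slope_m, x$intercept_b))
  if (!is.null(x$slope_interval)) {
    cat(sprintf("  95%% slope interval:     (%.4g, %.4g)\n",
                x$slope_interval[1], x$slope_interval[2]))
  }
  if (!is.null(x$intercept_interval)) {
    cat(sprintf("  95%% intercept interval: (%.5g, %.5g)\n",
                x$intercept_interval[1], x$intercept_interval[2]))
  }
  if (!is.na(x$r_squared)) cat(sprintf("  R^2 = %.3f\n", x$r_squared))
  cat(sprintf("  fitted support: [%g, %g] reference units\n",
              x$fitted_support[1], x$fitted_support[2]))
  invisible(x)
}

# evaluation window: linear evaluation is considered routine on [0, 120]
# reference units (and inside the fitted support if wider); above that a
# warning flags extrapolation, below 0 is an error.
.pion_eval_max <- function(cal) max(120, cal$fitted_support[2])

#' Evaluate the Pion calibration at a signal
#'
#' Returns `slope_m * s_star + intercept_b`. Evaluation is routine for
#' signals in `[0, 120]` reference units (the whole clinically occurring
#' range on the 100-unit scale); signals above that window raise a
#' warning, negative signals an error.
#'
#' @param s_star Renormalized uncorrected signal(s), >= 0.
#' @param cal A [pion_calibration()].
#' @return Pion value(s), dimensionless.
#' @export
pion_at_signal <- function(s_star, cal) {
  stopifnot(inherits(cal, "pion_calibration"))
  if (any(!is.finite(s_star)) || any(s_star < 0)) {
    stop("s_star must be finite and non-negative", call. = FALSE)
  }
  hi <- .pion_eval_max(cal)
  if (any(s_star > hi)) {
    warning(sprintf("evaluating Pion calibration beyond %g reference units",
                    hi), call. = FALSE)
  }
  cal$slope_m * s_star + cal$intercept_b
}

#' Convert an uncorrected signal to its recombination-corrected value
#'
#' Applies `S = Pion(S*) * S* = m (S*)^2 + b S*`; strictly increasing on
#' the evaluation window for non-negative slope and positive intercept.
#'
#' @inheritParams pion_at_signal
#' @return Corrected signal(s) on the same reference scale.
#' @seealso [uncorrect_signal()] for the exact inverse.
#' @export
correct_signal <- function(s_star, cal) {
  pion_at_signal(s_star, cal) * s_star
}

#' Recover the uncorrected signal from a corrected one
#'
#' Exact inverse of [correct_signal()]: solves `m x^2 + b x = S` for the
#' non-negative root,
#' \deqn{S^* = \frac{-b + \sqrt{b^2 + 4 m S}}{2 m},}
#' degenerating to `S / b` when the slope is zero. Useful for converting
#' corrected tabulated dose functions back to raw-signal form.
#'
#' @param s Corrected signal(s), >= 0.
#' @inheritParams pion_at_signal
#' @return Uncorrected signal(s) `s_star`.
#' @export
uncorrect_signal <- function(s, cal) {
  stopifnot(inherits(cal, "pion_calibration"))
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("s must be finite and non-negative", call. = FALSE)
  }
  m <- cal$slope_m
  b <- cal$intercept_b
  if (abs(m) < .Machine$double.eps) return(s / b)
  disc <- b^2 + 4 * m * s
  if (any(disc < 0)) {
    stop("corrected signal outside the range of the calibration ",
         "(negative discriminant)", call. = FALSE)
  }
  (-b + sqrt(disc)) / (2 * m)
}

# closed-form OLS on a resample matrix; rows are bootstrap replicates
.boot_ols <- function(x, y, n_boot, seed) {
  set.seed(seed)
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  xb <- matrix(x[idx], nrow = n_boot)
  yb <- matrix(y[idx], nrow = n_boot)
  mx <- rowMeans(xb)
  my <- rowMeans(yb)
  sxx <- rowSums(xb * xb) - n * mx * mx
  sxy <- rowSums(xb * yb) - n * mx * my
  slope <- sxy / sxx
  keep <- is.finite(slope)   # drop degenerate resamples (all-equal abscissae)
  slope <- slope[keep]
  intercept <- (my - (sxy / sxx) * mx)[keep]
  list(slope = slope, intercept = intercept)
}

.percentile_interval <- function(v) unname(stats::quantile(v, c(0.025, 0.975)))

#' Fit the linear Pion(signal) calibration
#'
#' Ordinary least squares fit of Pion against the renormalized
#' uncorrected signal, with 95% percentile intervals from a seeded
#' nonparametric bootstrap (resampling (signal, Pion) pairs).
#'
#' @param s_star Renormalized uncorrected signals (>= 3 values, not all
#'   equal).
#' @param pion Measured Pion values, same length.
#' @param energy_label Label stored in the resulting calibration.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap; mandatory for
#'   reproducibility.
#' @param v_high,v_low Voltage metadata recorded in the calibration.
#' @return A [pion_calibration()] with intervals, `r_squared` and
#'   `fitted_support` filled in.
#' @examples
#' s <- seq(10, 110, length.out = 10)
#' cal <- fit_pion_calibration(s, 1.5e-4 * s + 1, "demo", seed = 1)
#' pion_at_signal(100, cal)
#' @export
fit_pion_calibration <- function(s_star, pion, energy_label,
                                 n_boot = 2000, seed = 1L,
                                 v_high = 300, v_low = 150) {
  if (length(s_star) != length(pion)) {
    stop("s_star and pion must have the same length", call. = FALSE)
  }
  if (length(s_star) < 3L) {
    stop("at least 3 points are required to fit the calibration",
         call. = FALSE)
  }
  if (any(!is.finite(s_star)) || any(!is.finite(pion))) {
    stop("s_star and pion must be finite", call. = FALSE)
  }
  if (stats::var(s_star) == 0) {
    stop("degenerate abscissae: s_star values are all equal", call. = FALSE)
  }
  fit <- stats::lm(pion ~ s_star)
  co <- stats::coef(fit)
  bs <- .boot_ols(s_star, pion, n_boot, seed)
  pion_calibration(
    energy_label = energy_label,
    slope_m = unname(co[["s_star"]]),
    intercept_b = unname(co[["(Intercept)"]]),
    slope_interval = range(c(.percentile_interval(bs$slope), co[["s_star"]])),
    intercept_interval = range(c(.percentile_interval(bs$intercept),
                                 co[["(Intercept)"]])),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    fitted_support = range(s_star),
    v_high = v_high, v_low = v_low,
    n_points = length(s_star), seed = as.integer(seed)
  )
}

#' Test whether Pion depends on the monitor-unit rate
#'
#' The MU rate changes the pulse repetition frequency but not the dose
#' per pulse, so Pion should not depend on it. This fits an OLS slope of
#' Pion against MU rate with a seeded bootstrap 95% percentile interval
#' and reports whether the interval contains zero (zero being a credible
#' slope means no detectable MU-rate dependence).
#'
#' @param mu_rate Monitor-unit rates (MU/min); at least two distinct
#'   values.
#' @param pion Measured Pion values, same length.
#' @param n_boot,seed Bootstrap resamples and seed.
#' @return A list with `slope`, `interval` (length-2), `contains_zero`,
#'   and `n`.
#' @export
mu_rate_slope_test <- function(mu_rate, pion, n_boot = 2000, seed = 1L) {
  if (length(mu_rate) != length(pion)) {
    stop("mu_rate and pion must have the same length", call. = FALSE)
  }
  if (length(mu_rate) < 3L || length(unique(mu_rate)) < 2L) {
    stop("need >= 3 points spanning >= 2 distinct MU rates", call. = FALSE)
  }
  fit <- stats::lm(pion ~ mu_rate)
  slope <- unname(stats::coef(fit)[["mu_rate"]])
  bs <- .boot_ols(mu_rate, pion, n_boot, seed)
  iv <- range(c(.percentile_interval(bs$slope), slope))
  list(slope = slope, interval = iv,
       contains_zero = iv[1] <= 0 && 0 <= iv[2],
       n = length(mu_rate))
}
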