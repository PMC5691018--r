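# Synthetic FFF beam generator. The point is algebraic self-consistency,
# not transport physics: the *corrected* dose is modelled with a smooth
# buildup/attenuation/inverse-square shape, and the uncorrected signals
# are obtained by exactly inverting the prescribed linear Pion(signal)
# relation — so every correction stage has a known ground truth.

#' Parametric model of a synthetic FFF beam
#'
#' Depth dose is modelled as buildup times exponential attenuation under
#' inverse-square geometry,
#' `(1 - exp(-beta d)) exp(-mu d) / (ssd + d)^2`; crossplane profiles
#' are the cone shape characteristic of unflattened beams (linear
#' falloff from the CAX) rolled off through a Gaussian-integral
#' penumbra. The depth of maximum `dmax` is located numerically from the
#' depth shape.
#'
#' @param mu_eff Effective linear attenuation coefficient (1/cm, > 0).
#' @param beta_buildup Buildup rate constant (1/cm, > `mu_eff` so a
#'   maximum exists at positive depth).
#' @param cone_slope Fractional off-axis falloff per cm inside the field
#'   (1/cm).
#' @param penumbra_sigma Penumbra width parameter (cm, > 0).
#' @param ssd,sad Source-to-surface / source-to-axis distances (cm).
#' @return An object of class `beam_model` with the derived `dmax`.
#' @export
beam_model <- function(mu_eff = 0.044, beta_buildup = 2.2,
                       cone_slope = 0.012, penumbra_sigma = 0.3,
                       ssd = 100, sad = 100) {
  if (!is.finite(mu_eff) || mu_eff <= 0) stop("mu_eff must be > 0", call. = FALSE)
  if (!is.finite(beta_buildup) || beta_buildup <= mu_eff) {
    stop("beta_buildup must exceed mu_eff", call. = FALSE)
  }
  if (!is.finite(penumbra_sigma) || penumbra_sigma <= 0) {
    stop("penumbra_sigma must be > 0", call. = FALSE)
  }
  if (cone_slope < 0) stop("cone_slope must be >= 0", call. = FALSE)
  model <- list(mu_eff = mu_eff, beta_buildup = beta_buildup,
                cone_slope = cone_slope, penumbra_sigma = penumbra_sigma,
                ssd = ssd, sad = sad)
  shape <- function(d) {
    (1 - exp(-beta_buildup * d)) * exp(-mu_eff * d) / (ssd + d)^2
  }
  model$dmax <- stats::optimize(shape, c(0, 10), maximum = TRUE)$maximum
  structure(model, class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("<beam_model> mu = %g /cm, beta = %g /cm (dmax = %.2f cm), cone %g /cm, penumbra sigma %g cm\n",
              x$mu_eff, x$beta_buildup, x$dmax, x$cone_slope,
              x$penumbra_sigma))
  invisible(x)
}

#' Preset beam models
#'
#' Two fixture parameter sets loosely styled on high- and low-energy
#' unflattened beams; `"10fff"` penetrates more (smaller attenuation
#' coefficient) and has a steeper in-field cone than `"6fff"`. These are
#' synthetic test-bed constants, not commissioning data for any
#' clinical machine.
#'
#' @param name `"10fff"` or `"6fff"`.
#' @return A [beam_model()].
#' @export
beam_preset <- function(name = c("10fff", "6fff")) {
  switch(match.arg(name),
    "10fff" = beam_model(mu_eff = 0.044, beta_buildup = 2.2,
                         cone_slope = 0.012, penumbra_sigma = 0.3),
    "6fff"  = beam_model(mu_eff = 0.056, beta_buildup = 3.0,
                         cone_slope = 0.008, penumbra_sigma = 0.35)
  )
}

# relative depth-dose shape, = 1 at dmax
.depth_shape <- function(model, d) {
  f <- function(x) {
    (1 - exp(-model$beta_buildup * x)) * exp(-model$mu_eff * x) *
      ((model$ssd + model$dmax) / (model$ssd + x))^2
  }
  f(d) / f(model$dmax)
}

.truth_record <- function(cal, seed, ...) {
  structure(c(list(...), list(calibration = cal, seed = seed)),
            class = "truth_record")
}

#' Generate a synthetic depth-dose scan
#'
#' The noiseless *corrected* signal follows the beam model's depth
#' shape, scaled so that the corrected value at `dmax` maps back to an
#' uncorrected signal of exactly 100 reference units (the reference
#' convention). Uncorrected signals are obtained by exact inversion of
#' the calibration ([uncorrect_signal()]) and then perturbed with
#' multiplicative Gaussian noise.
#'
#' @param model A [beam_model()].
#' @param cal The generating [pion_calibration()].
#' @param depths Depth grid (cm) within `[0, 40]`.
#' @param noise_sd Fractional standard deviation of multiplicative
#'   Gaussian noise on the uncorrected signals (0 = noiseless).
#' @param seed Integer seed; generation is a pure function of
#'   (arguments, seed).
#' @return A list with `curve` (a depth-axis SSD [scan_curve()]) and
#'   `truth` (a `truth_record` holding the noiseless corrected and
#'   uncorrected signals, the true %dd, and the per-sample Pion values).
#' @export
generate_pdd <- function(model, cal, depths = seq(0, 35, by = 0.25),
                         noise_sd = 0, seed = 1L) {
  stopifnot(inherits(model, "beam_model"), inherits(cal, "pion_calibration"))
  if (any(depths < 0) || any(depths > 40)) {
    stop("depths must lie within [0, 40] cm", call. = FALSE)
  }
  depths <- sort(unique(c(depths, model$dmax)))
  s_corr <- correct_signal(100, cal) * .depth_shape(model, depths)
  s_unc <- uncorrect_signal(s_corr, cal)
  set.seed(seed)
  noisy <- pmax(0, s_unc * (1 + stats::rnorm(length(s_unc), 0, noise_sd)))
  list(
    curve = scan_curve("depth", depths, noisy,
                       energy_label = cal$energy_label, field_size = 10,
                       geometry = "SSD", nominal_distance = model$ssd),
    truth = .truth_record(cal, seed,
                          depths = depths,
                          corrected_signal = s_corr,
                          uncorrected_signal = s_unc,
                          pdd = 100 * s_corr / max(s_corr),
                          pion = pion_at_signal(s_unc, cal))
  )
}

#' Generate a synthetic crossplane profile
#'
#' The noiseless corrected profile is the CAX depth-dose value times a
#' cone factor `(1 - cone_slope |x|)` inside the field, rolled off
#' through a Gaussian-integral penumbra centred on the
#' divergence-projected field edge at the scan depth. Uncorrected
#' signals come from exact calibration inversion plus multiplicative
#' noise, as in [generate_pdd()].
#'
#' @inheritParams generate_pdd
#' @param field_size Square field side (cm), defined at the isocenter.
#' @param depth Scan depth (cm).
#' @param positions Crossplane grid (cm) extending beyond the projected
#'   field edge on both sides.
#' @return A list with `curve` (a crossplane [scan_curve()]) and
#'   `truth` (with the noiseless signals and true off-axis ratio).
#' @export
generate_profile <- function(model, cal, field_size = 10, depth = NULL,
                             positions = NULL, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(model, "beam_model"), inherits(cal, "pion_calibration"))
  if (is.null(depth)) depth <- model$dmax
  edge <- (field_size / 2) * (model$ssd + depth) / model$sad
  if (is.null(positions)) {
    positions <- seq(-edge - 3, edge + 3, by = 0.1)
  }
  if (min(positions) > -edge || max(positions) < edge) {
    stop("positions must extend beyond the projected field edges",
         call. = FALSE)
  }
  positions <- sort(unique(c(positions, 0)))  # exact CAX sample
  cax <- correct_signal(100, cal) * .depth_shape(model, depth)
  cone <- pmax(0, 1 - model$cone_slope * abs(positions))
  pen <- stats::pnorm((edge - abs(positions)) / model$penumbra_sigma)
  s_corr <- cax * cone * pen
  s_unc <- uncorrect_signal(s_corr, cal)
  set.seed(seed)
  noisy <- pmax(0, s_unc * (1 + stats::rnorm(length(s_unc), 0, noise_sd)))
  list(
    curve = scan_curve("crossplane", positions, noisy,
                       energy_label = cal$energy_label,
                       field_size = field_size, geometry = "SSD",
                       nominal_distance = model$ssd, depth_of_curve = depth),
    truth = .truth_record(cal, seed,
                          positions = positions,
                          corrected_signal = s_corr,
                          uncorrected_signal = s_unc,
                          oar = 100 * s_corr / s_corr[positions == 0],
                          projected_edge = edge)
  )
}

#' Generate two-voltage reading pairs consistent with a calibration
#'
#' For each uncorrected signal the true Pion is `m S* + b`; the
#' high-voltage reading is the signal itself (reference units) and the
#' low-voltage reading follows from exact algebraic inversion of the
#' two-voltage formula, `M*_low = M*_high / (Vr + (1 - Vr)/Pion)` with
#' `Vr = v_high/v_low`. On noiseless output,
#' [compute_pion_two_voltage()] recovers the true Pion to machine
#' precision. Noise is multiplicative Gaussian, independent between the
#' two readings.
#'
#' @param s_star Uncorrected renormalized signals (>= 0).
#' @inheritParams generate_pdd
#' @param v_high,v_low Bias voltages (V).
#' @return A list with `readings` (a data.frame with columns
#'   `s_star_context`, `v_high`, `v_low`, `m_high`, `m_low`) and
#'   `truth` (with the true Pion per reading).
#' @export
generate_two_voltage_set <- function(s_star, cal, v_high = 300, v_low = 150,
                                     noise_sd = 0, seed = 1L) {
  stopifnot(inherits(cal, "pion_calibration"))
  if (any(s_star < 0)) stop("s_star must be non-negative", call. = FALSE)
  vr <- v_high / v_low
  if (!is.finite(vr) || vr <= 1) {
    stop("v_high must exceed v_low > 0", call. = FALSE)
  }
  pion <- cal$slope_m * s_star + cal$intercept_b
  if (any(pion <= (vr - 1) / vr)) {
    stop("Pion at or below the two-voltage limit (vr - 1)/vr; readings ",
         "would be non-physical", call. = FALSE)
  }
  m_high <- s_star
  m_low <- m_high / (vr + (1 - vr) / pion)
  set.seed(seed)
  n <- length(s_star)
  readings <- data.frame(
    s_star_context = s_star,
    v_high = v_high, v_low = v_low,
    m_high = m_high * (1 + stats::rnorm(n, 0, noise_sd)),
    m_low = m_low * (1 + stats::rnorm(n, 0, noise_sd))
  )
  list(readings = readings,
       truth = .truth_record(cal, seed, s_star = s_star, pion = pion,
                             m_high = m_high, m_low = m_low))
}

#' Generate Pion-vs-MU-rate measurements under the null
#'
#' Constant true Pion across monitor-unit rates plus Gaussian noise —
#' the null hypothesis that recombination does not depend on pulse
#' repetition frequency. An optional linear trend can be injected to
#' exercise the power of [mu_rate_slope_test()].
#'
#' @param mu_rates Distinct MU rates (MU/min).
#' @param true_pion Constant Pion value (default 1.010).
#' @param noise_sd Additive Gaussian noise SD on Pion (default 5e-4).
#' @param reps Replicate measurements per MU rate (default 10).
#' @param seed Integer seed.
#' @param trend Injected slope per MU/min (default 0 = null).
#' @return A data.frame with columns `mu_rate` and `pion`.
#' @export
generate_mu_rate_set <- function(mu_rates = c(400, 800, 1200, 1600, 2400),
                                 true_pion = 1.010, noise_sd = 5e-4,
                                 reps = 10, seed = 7L, trend = 0) {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  mu <- rep(mu_rates, each = reps)
  set.seed(seed)
  data.frame(
    mu_rate = mu,
    pion = true_pion + trend * mu + stats::rnorm(length(mu), 0, noise_sd)
  )
}
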