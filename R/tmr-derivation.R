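# Deriving TMR from %dd scans: the chamber never sits at the isocenter
# during an SSD depth scan, so the TMR at depth d is computed at a point
# (sad + d) cm from the source, and the recombination correction must be
# evaluated at those *calculated* signal magnitudes — which differ from
# the magnitudes a direct SAD measurement would read.

#' Configuration for TMR derivation from a depth-dose scan
#'
#' @param sad Source-axis distance (cm), default 100.
#' @param scatter_factor Optional multiplicative correction applied to
#'   the calculated signals beyond the inverse-square factor
#'   (dimensionless, default 1). Phantom-scatter differences between the
#'   SSD and the derived geometry are of this form but have no universal
#'   functional form; it cancels in the TMR ratio and only shifts the
#'   signal magnitudes at which Pion is evaluated.
#' @param apply_pion Apply the recombination correction (default TRUE).
#' @return A list of class `tmr_config`.
#' @export
tmr_config <- function(sad = 100, scatter_factor = 1, apply_pion = TRUE) {
  if (!is.finite(sad) || sad <= 0) stop("sad must be positive", call. = FALSE)
  if (!is.finite(scatter_factor) || scatter_factor <= 0) {
    stop("scatter_factor must be positive", call. = FALSE)
  }
  structure(list(sad = sad, scatter_factor = scatter_factor,
                 apply_pion = isTRUE(apply_pion)),
            class = "tmr_config")
}

#' Derive a TMR curve from a percent-depth-dose scan
#'
#' Maps an SSD depth scan to tissue-maximum ratios at the isocenter
#' plane. Each depth `d` is evaluated at a point `(sad + d)` cm from the
#' source: starting from SAD-scale signals
#' `S*_ref(d) = 100 S*(d) (ssd + d)^2 / (S*(dmax) (ssd + dmax)^2)`
#' (the 100-unit reference convention fixes the SAD dmax signal at 100),
#' the calculated signals at the derived point are
#' \deqn{S^*_{calc}(d) = S^*_{ref}(d)\,\Big(\frac{sad}{sad+d}\Big)^2 f_s,}
#' with `f_s` the scatter factor, and likewise for the dmax point
#' (`S*_ref = 100`) pushed to the same source distance. The uncorrected
#' TMR is the ratio of calculated signals (the inverse-square factors
#' cancel, recovering the classic %dd-to-TMR conversion); the corrected
#' TMR applies the calibrated Pion at the calculated magnitudes:
#' \deqn{TMR(d) = \frac{S^*_{calc}(d) P_{ion}(S^*_{calc}(d))}
#'   {S^*_{calc,dmax}(d) P_{ion}(S^*_{calc,dmax}(d))}.}
#' Because Pion depends on signal magnitude, the correction obtained
#' this way differs from the one a directly measured SAD scan would
#' receive — the returned magnitudes let users compare the two.
#'
#' @param curve A depth-axis, SSD-geometry [scan_curve()].
#' @param cal A [pion_calibration()].
#' @param config A [tmr_config()].
#' @return A list with `corrected` and `uncorrected`
#'   [dose_function_curve()]s of kind `"tmr"`, and a data.frame
#'   `signals` with columns `depth_cm`, `s_star_calc_depth`,
#'   `s_star_calc_dmax`.
#' @export
derive_tmr_from_pdd <- function(curve, cal, config = tmr_config()) {
  stopifnot(inherits(curve, "scan_curve"), inherits(cal, "pion_calibration"),
            inherits(config, "tmr_config"))
  if (curve$axis != "depth" || curve$geometry != "SSD") {
    stop("derive_tmr_from_pdd needs an SSD depth scan", call. = FALSE)
  }
  .check_energy(curve$energy_label, cal)
  d <- curve$positions
  s <- curve$signals
  if (all(s == 0)) stop("all-zero signals", call. = FALSE)
  ssd <- curve$nominal_distance
  sad <- config$sad
  i_max <- which.max(s)
  d_max <- d[i_max]
  # SAD-scale signal at depth d (chamber at the isocenter under depth d
  # of water), anchored to the 100-unit reference at dmax
  s_ref <- 100 * (s * (ssd + d)^2) / (s[i_max] * (ssd + d_max)^2)
  if (any(s_ref <= 0 & d > d_max)) {
    stop("zero signal beyond the depth of maximum", call. = FALSE)
  }
  isq <- (sad / (sad + d))^2
  s_calc_depth <- s_ref * isq * config$scatter_factor
  s_calc_dmax <- 100 * isq * config$scatter_factor
  tmr_unc <- s_calc_depth / s_calc_dmax
  tmr_cor <- if (config$apply_pion) {
    correct_signal(s_calc_depth, cal) / correct_signal(s_calc_dmax, cal)
  } else {
    tmr_unc
  }
  list(
    corrected = dose_function_curve(d, tmr_cor, "tmr", corrected = TRUE,
                                    energy_label = curve$energy_label),
    uncorrected = dose_function_curve(d, tmr_unc, "tmr", corrected = FALSE,
                                      energy_label = curve$energy_label),
    signals = data.frame(depth_cm = d,
                         s_star_calc_depth = s_calc_depth,
                         s_star_calc_dmax = s_calc_dmax)
  )
}
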