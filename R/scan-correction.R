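# Applying a Pion calibration to scan curves and point readings.
#
# Every correction here is a ratio of corrected signals, so it reduces to
# the identity when the calibration slope is zero: the Pion ratio cancels.

.check_energy <- function(curve_label, cal) {
  if (nzchar(curve_label) && nzchar(cal$energy_label) &&
      curve_label != cal$energy_label) {
    stop(sprintf("calibration energy '%s' does not match curve energy '%s'",
                 cal$energy_label, curve_label), call. = FALSE)
  }
}

.corrected_pair <- function(positions, corrected, uncorrected, kind,
                            energy_label, depth_of_curve = NA_real_) {
  list(
    corrected = dose_function_curve(positions, corrected, kind,
                                    corrected = TRUE,
                                    energy_label = energy_label,
                                    depth_of_curve = depth_of_curve),
    uncorrected = dose_function_curve(positions, uncorrected, kind,
                                      corrected = FALSE,
                                      energy_label = energy_label,
                                      depth_of_curve = depth_of_curve)
  )
}

#' Correct a percent-depth-dose curve for ion recombination
#'
#' The depth of dose maximum is located as the global signal maximum of
#' the scan. The uncorrected curve is the plain signal ratio,
#' `100 S*(d) / S*(dmax)`; the corrected curve multiplies numerator and
#' denominator by the calibrated Pion at their respective signal
#' magnitudes,
#' \deqn{\%dd(d) = 100\,\frac{S^*(d) P_{ion}(S^*(d))}
#'   {S^*(d_{max}) P_{ion}(S^*(d_{max}))},}
#' and both curves are renormalized so their own maximum is exactly 100.
#'
#' @param curve A depth-axis, SSD-geometry [scan_curve()].
#' @param cal A [pion_calibration()] whose energy label matches the
#'   curve's (empty labels match anything).
#' @return A list with `corrected` and `uncorrected`
#'   [dose_function_curve()]s of kind `"pdd"`.
#' @export
correct_pdd <- function(curve, cal) {
  stopifnot(inherits(curve, "scan_curve"), inherits(cal, "pion_calibration"))
  if (curve$axis != "depth") stop("correct_pdd needs a depth scan", call. = FALSE)
  if (curve$geometry != "SSD") {
    stop("percent depth dose is defined for SSD geometry (use correct_tmr ",
         "for SAD scans)", call. = FALSE)
  }
  .check_energy(curve$energy_label, cal)
  s <- curve$signals
  if (all(s == 0)) stop("all-zero signals", call. = FALSE)
  corr <- correct_signal(s, cal)
  .corrected_pair(curve$positions,
                  100 * corr / max(corr),
                  100 * s / max(s),
                  "pdd", curve$energy_label)
}

#' Correct a tissue-maximum-ratio curve for ion recombination
#'
#' For SAD-geometry depth scans (chamber fixed at isocenter, water added
#' above it). The TMR is the corrected-signal ratio to the depth of dose
#' maximum; unlike [correct_pdd()] the result is left as a raw ratio in
#' `(0, 1]`, not rescaled to percent.
#'
#' @param curve A depth-axis, SAD-geometry [scan_curve()].
#' @inheritParams correct_pdd
#' @return A list with `corrected` and `uncorrected`
#'   [dose_function_curve()]s of kind `"tmr"`.
#' @export
correct_tmr <- function(curve, cal) {
  stopifnot(inherits(curve, "scan_curve"), inherits(cal, "pion_calibration"))
  if (curve$axis != "depth") stop("correct_tmr needs a depth scan", call. = FALSE)
  if (curve$geometry != "SAD") {
    stop("TMR is defined for SAD geometry", call. = FALSE)
  }
  .check_energy(curve$energy_label, cal)
  s <- curve$signals
  if (all(s == 0)) stop("all-zero signals", call. = FALSE)
  corr <- correct_signal(s, cal)
  .corrected_pair(curve$positions,
                  corr / max(corr),
                  s / max(s),
                  "tmr", curve$energy_label)
}

#' Correct an off-axis-ratio profile for ion recombination
#'
#' The central-axis signal is taken by linear interpolation at position
#' zero (FFF profiles peak on-axis, but the CAX sample itself defines
#' the normalization). Corrected and uncorrected profiles are both
#' normalized to 100 on the CAX. With a positive calibration slope the
#' off-axis Pion ratio is below one wherever the signal is below the CAX
#' signal, so the correction lowers the shoulders and technically
#' narrows the field.
#'
#' @param curve A crossplane [scan_curve()] whose positions span 0.
#' @inheritParams correct_pdd
#' @return A list with `corrected` and `uncorrected`
#'   [dose_function_curve()]s of kind `"oar"`.
#' @export
correct_oar <- function(curve, cal) {
  stopifnot(inherits(curve, "scan_curve"), inherits(cal, "pion_calibration"))
  if (curve$axis != "crossplane") {
    stop("correct_oar needs a crossplane scan", call. = FALSE)
  }
  if (min(curve$positions) > 0 || max(curve$positions) < 0) {
    stop("central axis (position 0) outside the scanned range", call. = FALSE)
  }
  .check_energy(curve$energy_label, cal)
  s <- curve$signals
  s_cax <- stats::approx(curve$positions, s, xout = 0, ties = "ordered")$y
  if (s_cax <= 0) stop("central-axis signal must be positive", call. = FALSE)
  corr <- correct_signal(s, cal)
  corr_cax <- correct_signal(s_cax, cal)
  .corrected_pair(curve$positions,
                  100 * corr / corr_cax,
                  100 * s / s_cax,
                  "oar", curve$energy_label, curve$depth_of_curve)
}

#' Correct relative dose factors for ion recombination
#'
#' The relative dose factor (RDF) compares the signal for a field size
#' to the 10x10 cm^2 reference field. Because the two signals are within
#' about ten reference units of each other, the Pion ratio is close to
#' one and the correction is of order 1e-3.
#'
#' @param field_size Square field sides (cm); must include
#'   `reference_field_size`.
#' @param s_star Uncorrected renormalized signals at dmax for each
#'   field.
#' @param cal A [pion_calibration()].
#' @param reference_field_size Reference field side (cm), default 10.
#' @param energy_label Optional label checked against the calibration.
#' @return A list with `corrected` and `uncorrected`
#'   [dose_function_curve()]s of kind `"rdf"` (positions are field
#'   sides).
#' @export
correct_rdf <- function(field_size, s_star, cal, reference_field_size = 10,
                        energy_label = "") {
  stopifnot(inherits(cal, "pion_calibration"))
  if (length(field_size) != length(s_star)) {
    stop("field_size and s_star must have the same length", call. = FALSE)
  }
  .check_energy(energy_label, cal)
  i_ref <- which(field_size == reference_field_size)
  if (length(i_ref) == 0L) {
    stop(sprintf("reference field size %g cm not among the readings",
                 reference_field_size), call. = FALSE)
  }
  i_ref <- i_ref[1]
  o <- order(field_size)
  fs <- field_size[o]
  s <- s_star[o]
  corr <- correct_signal(s, cal)
  .corrected_pair(fs,
                  corr / correct_signal(s_star[i_ref], cal),
                  s / s_star[i_ref],
                  "rdf", energy_label)
}

#' Absolute and relative difference between corrected and uncorrected
#' dose functions
#'
#' For a dose function `f` and its uncorrected twin `f*` on the same
#' grid, computes the pointwise absolute difference `f - f*` and the
#' relative difference `100 (f - f*) / f` (percent, relative to the
#' corrected value; `NA` where the corrected value is zero).
#'
#' @param corrected,uncorrected [dose_function_curve()]s of the same
#'   kind on identical position grids.
#' @return An object of class `difference_curve` with fields
#'   `positions`, `delta_abs`, `delta_rel`, `kind`.
#' @export
difference_curves <- function(corrected, uncorrected) {
  stopifnot(inherits(corrected, "dose_function_curve"),
            inherits(uncorrected, "dose_function_curve"))
  if (corrected$kind != uncorrected$kind) {
    stop("curves must be of the same kind", call. = FALSE)
  }
  if (length(corrected$positions) != length(uncorrected$positions) ||
      any(corrected$positions != uncorrected$positions)) {
    stop("curves must share the same position grid", call. = FALSE)
  }
  d_abs <- corrected$values - uncorrected$values
  d_rel <- ifelse(corrected$values > 0,
                  100 * d_abs / corrected$values, NA_real_)
  structure(
    list(positions = corrected$positions, delta_abs = d_abs,
         delta_rel = d_rel, kind = corrected$kind),
    class = "difference_curve"
  )
}

#' @export
print.difference_curve <- function(x, ...) {
  cat(sprintf("<difference_curve> %s: max |delta_abs| %.4g, max |delta_rel| %.4g%%\n",
              toupper(x$kind), max(abs(x$delta_abs)),
              max(abs(x$delta_rel), na.rm = TRUE)))
  invisible(x)
}

# walk outward from the CAX along one side of a CAX-normalized profile
# and locate the first samples bracketing the 50% level
.half_crossing <- function(dist, val, v0) {
  d <- c(0, dist)
  v <- c(v0, val)
  for (k in seq_len(length(d) - 1L)) {
    if (v[k] >= 50 && v[k + 1L] < 50) {
      return(d[k] + (50 - v[k]) * (d[k + 1L] - d[k]) / (v[k + 1L] - v[k]))
    }
  }
  stop("profile never crosses the 50% level on one side", call. = FALSE)
}

#' Locate the 50%-isodose field edges of a profile
#'
#' For a CAX-normalized profile (central axis = 100), finds the left and
#' right positions where the profile crosses 50%, by linear
#' interpolation between the first bracketing sample pair encountered
#' moving outward from the CAX (robust to noise-induced re-crossings in
#' the tails). The field width is the distance between the two
#' crossings.
#'
#' @param profile A [dose_function_curve()] of kind `"oar"` (or any
#'   profile normalized to 100 on the CAX) spanning position 0.
#' @return A list with `left`, `right` (cm) and `width` (cm).
#' @export
field_width_50 <- function(profile) {
  stopifnot(inherits(profile, "dose_function_curve"))
  p <- profile$positions
  v <- profile$values
  if (min(p) > 0 || max(p) < 0) {
    stop("profile must span the central axis (position 0)", call. = FALSE)
  }
  v0 <- stats::approx(p, v, xout = 0, ties = "ordered")$y
  if (v0 < 50) stop("central-axis value below 50%", call. = FALSE)
  right <- .half_crossing(p[p > 0], v[p > 0], v0)
  iL <- p < 0
  left <- -.half_crossing(rev(-p[iL]), rev(v[iL]), v0)
  list(left = left, right = right, width = right - left)
}

#' Field-width change due to the recombination correction
#'
#' Corrects a crossplane scan with [correct_oar()], measures the
#' 50%-isodose width of both the corrected and the uncorrected profile
#' with [field_width_50()], and reports the change
#' `delta_w = w - w*`. A positive calibration slope narrows the field
#' (`delta_w <= 0`), though for clinical FFF calibrations the change is
#' hundredths of a millimetre.
#'
#' @inheritParams correct_oar
#' @return An object of class `width_result` with fields
#'   `width_corrected`, `width_uncorrected`, `delta_w` (all cm), and the
#'   left/right crossing coordinates of both profiles.
#' @export
width_delta <- function(curve, cal) {
  pair <- correct_oar(curve, cal)
  wc <- field_width_50(pair$corrected)
  wu <- field_width_50(pair$uncorrected)
  structure(
    list(width_corrected = wc$width, width_uncorrected = wu$width,
         delta_w = wc$width - wu$width,
         left_corrected = wc$left, right_corrected = wc$right,
         left_uncorrected = wu$left, right_uncorrected = wu$right),
    class = "width_result"
  )
}

#' @export
print.width_result <- function(x, ...) {
  cat(sprintf("<width_result> w = %.4f cm, w* = %.4f cm, delta_w = %+.4f cm (%+.2f mm)\n",
              x$width_corrected, x$width_uncorrected,
              x$delta_w, 10 * x$delta_w))
  invisible(x)
}
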