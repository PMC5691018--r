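# Quality-conversion (kQ) chain: because kQ is indexed by %dd(10), the
# recombination correction to a depth-dose curve propagates into the
# absolute dose calibration.

#' Quality-conversion lookup table for one chamber model
#'
#' An ordered grid of (%dd(10), kQ) pairs for linear interpolation, as
#' tabulated by dosimetry protocols per chamber model. Protocol tables
#' are external inputs (see [read_kq_table_csv()]); they are not shipped
#' with the package.
#'
#' @param chamber_model Chamber model name (e.g. `"IC10"`).
#' @param pdd10 Strictly increasing %dd(10) abscissae (percent).
#' @param kq Quality-conversion factors, each in (0.9, 1.05).
#' @return An object of class `quality_conversion_table`.
#' @export
quality_conversion_table <- function(chamber_model, pdd10, kq) {
  pdd10 <- as.numeric(pdd10)
  kq <- as.numeric(kq)
  if (length(pdd10) != length(kq) || length(pdd10) < 2L) {
    stop("pdd10 and kq must be equal-length vectors (n >= 2)", call. = FALSE)
  }
  if (any(diff(pdd10) <= 0)) {
    stop("pdd10 abscissae must be strictly increasing", call. = FALSE)
  }
  if (any(kq <= 0.9) || any(kq >= 1.05)) {
    stop("kq values must lie in (0.9, 1.05)", call. = FALSE)
  }
  structure(list(chamber_model = as.character(chamber_model),
                 pdd10 = pdd10, kq = kq),
            class = "quality_conversion_table")
}

#' @export
print.quality_conversion_table <- function(x, ...) {
  cat(sprintf("<quality_conversion_table> %s: %d grid points, %%dd(10) in [%g, %g]\n",
              x$chamber_model, length(x$pdd10), min(x$pdd10), max(x$pdd10)))
  invisible(x)
}

#' Interpolate the quality-conversion factor kQ at a beam quality
#'
#' Piecewise-linear interpolation of kQ at the given %dd(10); exact at
#' grid points. No extrapolation: a beam quality outside the table's
#' range is an error.
#'
#' @param pdd10 Percent depth dose at 10 cm depth (the beam-quality
#'   specifier), within the table's range.
#' @param table A [quality_conversion_table()].
#' @return Interpolated kQ value(s).
#' @export
interpolate_kq <- function(pdd10, table) {
  stopifnot(inherits(table, "quality_conversion_table"))
  if (any(pdd10 < min(table$pdd10)) || any(pdd10 > max(table$pdd10))) {
    stop("pdd10 outside the table's range; refusing to extrapolate kQ",
         call. = FALSE)
  }
  stats::approx(table$pdd10, table$kq, xout = pdd10, ties = "ordered")$y
}

#' Relative change in kQ (and hence in absolute dose rate)
#'
#' `100 (kQ - kQ*) / kQ*`, in percent. Since the absolute dose is
#' proportional to kQ, the relative change in kQ equals the relative
#' change in the calibrated dose rate.
#'
#' @param kq_uncorrected kQ from the uncorrected %dd(10) (> 0).
#' @param kq_corrected kQ from the recombination-corrected %dd(10)
#'   (> 0).
#' @return Percent change (positive when the correction raises kQ).
#' @export
relative_kq_change <- function(kq_uncorrected, kq_corrected) {
  if (any(kq_uncorrected <= 0) || any(kq_corrected <= 0)) {
    stop("kQ values must be positive", call. = FALSE)
  }
  100 * (kq_corrected - kq_uncorrected) / kq_uncorrected
}

#' Absolute dose from a fully corrected reading
#'
#' `Dw = M kQ N_Dw`: the fully corrected chamber reading times the
#' quality-conversion factor times the absorbed-dose-to-water
#' calibration coefficient.
#'
#' @param m_corrected Fully corrected reading (charge units, > 0).
#' @param kq Quality-conversion factor (> 0).
#' @param nd_w Absorbed-dose-to-water calibration coefficient (Gy per
#'   charge unit, > 0).
#' @return Dose to water (Gy).
#' @export
absolute_dose <- function(m_corrected, kq, nd_w) {
  if (any(m_corrected <= 0) || any(kq <= 0) || any(nd_w <= 0)) {
    stop("all factors must be positive", call. = FALSE)
  }
  m_corrected * kq * nd_w
}
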