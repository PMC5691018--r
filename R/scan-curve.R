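# Containers for 1-D water-tank scan data and derived dose functions.

#' A 1-D beam scan on the renormalized signal scale
#'
#' Ordered (position, uncorrected renormalized signal) samples together
#' with the geometry metadata a correction needs. Depth scans run along
#' the central axis (positions are depths in cm, positive downward);
#' crossplane scans run perpendicular to it at a fixed depth, with
#' position 0 on the central axis (CAX).
#'
#' Signals are stored uncorrected, on the 100-unit reference scale
#' (see [reference_scale()]); conversion from raw electrometer units
#' belongs at ingest.
#'
#' @param axis `"depth"` or `"crossplane"`.
#' @param positions Strictly increasing sample coordinates (cm).
#' @param signals Uncorrected renormalized signals `S*` (>= 0), same
#'   length as `positions`.
#' @param energy_label Beam-energy group name (e.g. `"10FFF"`).
#' @param field_size Square field side length (cm).
#' @param geometry `"SSD"` or `"SAD"`.
#' @param nominal_distance Source-to-surface or source-to-axis distance
#'   (cm), default 100.
#' @param depth_of_curve Depth of a crossplane scan (cm); `NA` for depth
#'   scans.
#' @return An object of class `scan_curve`.
#' @export
scan_curve <- function(axis, positions, signals, energy_label = "",
                       field_size = 10, geometry = c("SSD", "SAD"),
                       nominal_distance = 100, depth_of_curve = NA_real_) {
  axis <- match.arg(axis, c("depth", "crossplane"))
  geometry <- match.arg(geometry)
  positions <- as.numeric(positions)
  signals <- as.numeric(signals)
  if (length(positions) != length(signals) || length(positions) < 2L) {
    stop("positions and signals must be equal-length vectors (n >= 2)",
         call. = FALSE)
  }
  if (any(!is.finite(positions)) || any(diff(positions) <= 0)) {
    stop("positions must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(signals)) || any(signals < 0)) {
    stop("signals must be finite and non-negative", call. = FALSE)
  }
  if (axis == "depth" && any(positions < 0)) {
    stop("depth-axis positions must be non-negative", call. = FALSE)
  }
  if (!is.finite(nominal_distance) || nominal_distance <= 0) {
    stop("nominal_distance must be positive", call. = FALSE)
  }
  if (axis == "crossplane" && is.na(depth_of_curve)) {
    stop("crossplane scans need depth_of_curve", call. = FALSE)
  }
  structure(
    list(axis = axis, positions = positions, signals = signals,
         energy_label = as.character(energy_label),
         field_size = as.numeric(field_size), geometry = geometry,
         nominal_distance = as.numeric(nominal_distance),
         depth_of_curve = as.numeric(depth_of_curve)),
    class = "scan_curve"
  )
}

#' @export
print.scan_curve <- function(x, ...) {
  cat(sprintf("<scan_curve> %s axis, %d samples on [%g, %g] cm\n",
              x$axis, length(x$positions), min(x$positions), max(x$positions)))
  cat(sprintf("  %s  %gx%g cm^2  %s %g cm%s\n",
              if (nzchar(x$energy_label)) x$energy_label else "(unlabelled)",
              x$field_size, x$field_size, x$geometry, x$nominal_distance,
              if (!is.na(x$depth_of_curve))
                sprintf("  at depth %g cm", x$depth_of_curve) else ""))
  invisible(x)
}

#' @export
as.data.frame.scan_curve <- function(x, ...) {
  data.frame(position_cm = x$positions, signal = x$signals)
}

#' A dose function derived from scan data
#'
#' Holds one dosimetric function on a position grid: percent depth dose
#' (`pdd`, percent, max 100), tissue-maximum ratio (`tmr`, ratio in
#' (0, 1]), off-axis ratio (`oar`, percent, 100 on the CAX), or relative
#' dose factor (`rdf`, ratio, 1 at the reference field size — positions
#' then hold field sizes in cm).
#'
#' @param positions Sample coordinates (cm; field sides for `rdf`).
#' @param values Function values.
#' @param kind One of `"pdd"`, `"tmr"`, `"oar"`, `"rdf"`.
#' @param corrected Logical: has the recombination correction been
#'   applied?
#' @param energy_label,depth_of_curve Carried metadata.
#' @return An object of class `dose_function_curve`.
#' @export
dose_function_curve <- function(positions, values,
                                kind = c("pdd", "tmr", "oar", "rdf"),
                                corrected = FALSE, energy_label = "",
                                depth_of_curve = NA_real_) {
  kind <- match.arg(kind)
  positions <- as.numeric(positions)
  values <- as.numeric(values)
  if (length(positions) != length(values)) {
    stop("positions and values must have the same length", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  structure(
    list(positions = positions, values = values, kind = kind,
         corrected = isTRUE(corrected),
         energy_label = as.character(energy_label),
         depth_of_curve = as.numeric(depth_of_curve)),
    class = "dose_function_curve"
  )
}

#' @export
print.dose_function_curve <- function(x, ...) {
  cat(sprintf("<dose_function_curve> %s (%s), %d samples on [%g, %g]\n",
              toupper(x$kind), if (x$corrected) "corrected" else "uncorrected",
              length(x$positions), min(x$positions), max(x$positions)))
  invisible(x)
}

#' @export
as.data.frame.dose_function_curve <- function(x, ...) {
  data.frame(position = x$positions, value = x$values)
}

#' Evaluate a dose function curve at arbitrary positions
#'
#' Linear interpolation between samples; positions outside the grid are
#' an error (dose functions are not extrapolated).
#'
#' @param curve A [dose_function_curve()].
#' @param at Positions (cm) at which to evaluate.
#' @return Interpolated values.
#' @export
dose_function_at <- function(curve, at) {
  stopifnot(inherits(curve, "dose_function_curve"))
  if (any(at < min(curve$positions)) || any(at > max(curve$positions))) {
    stop("position outside the curve's range", call. = FALSE)
  }
  stats::approx(curve$positions, curve$values, xout = at, ties = "ordered")$y
}
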