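# Readers and writers: the scan CSV dialect, calibration JSON, kQ table
# CSV, and two-voltage / RDF point-reading CSVs. Parsers validate
# strictly and reject malformed numeric fields rather than coercing.

.fmt_num <- function(x) sprintf("%.10g", x)

.read_meta_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta_raw <- sub("^#\\s*", "", lines[is_meta])
  kv <- strsplit(meta_raw, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed metadata line: '", meta_raw[bad][1], "'", call. = FALSE)
  }
  meta <- vapply(kv, function(p) trimws(p[2]), "")
  names(meta) <- vapply(kv, function(p) trimws(p[1]), "")
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("no data rows in ", path, call. = FALSE)
  list(meta = meta, body = body)
}

.require_meta <- function(meta, keys, path) {
  missing <- setdiff(keys, names(meta))
  if (length(missing)) {
    stop(sprintf("missing required metadata key(s) in %s: %s",
                 path, paste0("'", missing, "'", collapse = ", ")),
         call. = FALSE)
  }
}

.num_meta <- function(meta, key) {
  v <- suppressWarnings(as.numeric(meta[[key]]))
  if (is.na(v)) stop("metadata key '", key, "' is not numeric", call. = FALSE)
  v
}

.read_body <- function(body, expected_cols) {
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = "numeric")
  if (!identical(names(df), expected_cols)) {
    stop("expected header '", paste(expected_cols, collapse = ","),
         "', found '", paste(names(df), collapse = ","), "'", call. = FALSE)
  }
  df
}

#' Read a beam scan from the scan CSV dialect
#'
#' The dialect is `# key=value` metadata lines (`axis`, `energy`,
#' `field_cm`, `geometry`, `distance_cm`, plus `depth_cm` for crossplane
#' scans), then a `position_cm,signal` header and numeric rows. Signals
#' are uncorrected renormalized values on the 100-unit reference scale.
#'
#' @param path Path to the CSV file.
#' @return A [scan_curve()].
#' @seealso [write_scan_csv()]
#' @export
read_scan_csv <- function(path) {
  parsed <- .read_meta_csv(path)
  meta <- parsed$meta
  .require_meta(meta, c("axis", "energy", "field_cm", "geometry",
                        "distance_cm"), path)
  axis <- meta[["axis"]]
  if (axis == "crossplane") .require_meta(meta, "depth_cm", path)
  df <- .read_body(parsed$body, c("position_cm", "signal"))
  scan_curve(
    axis = axis, positions = df$position_cm, signals = df$signal,
    energy_label = meta[["energy"]],
    field_size = .num_meta(meta, "field_cm"),
    geometry = meta[["geometry"]],
    nominal_distance = .num_meta(meta, "distance_cm"),
    depth_of_curve = if (axis == "crossplane") .num_meta(meta, "depth_cm")
                     else NA_real_
  )
}

#' Write a beam scan in the scan CSV dialect
#'
#' Canonical formatting: fixed metadata order, `%.10g` numbers. When
#' `corrected` is supplied (a vector of corrected signals on the same
#' grid) a third column `signal_corrected` is emitted.
#'
#' @param curve A [scan_curve()].
#' @param path Output path.
#' @param corrected Optional corrected signals, same length as the
#'   curve.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(curve, path, corrected = NULL) {
  stopifnot(inherits(curve, "scan_curve"))
  meta <- c(sprintf("# axis=%s", curve$axis),
            sprintf("# energy=%s", curve$energy_label),
            sprintf("# field_cm=%s", .fmt_num(curve$field_size)),
            sprintf("# geometry=%s", curve$geometry),
            sprintf("# distance_cm=%s", .fmt_num(curve$nominal_distance)))
  if (curve$axis == "crossplane") {
    meta <- c(meta, sprintf("# depth_cm=%s", .fmt_num(curve$depth_of_curve)))
  }
  if (is.null(corrected)) {
    header <- "position_cm,signal"
    rows <- paste(.fmt_num(curve$positions), .fmt_num(curve$signals),
                  sep = ",")
  } else {
    stopifnot(length(corrected) == length(curve$signals))
    header <- "position_cm,signal,signal_corrected"
    rows <- paste(.fmt_num(curve$positions), .fmt_num(curve$signals),
                  .fmt_num(corrected), sep = ",")
  }
  writeLines(c(meta, header, rows), path)
  invisible(path)
}

#' Read or write a Pion calibration as JSON
#'
#' The JSON schema has keys `energy_label`, `slope_m`, `intercept_b`,
#' `slope_interval`, `intercept_interval`, `r_squared`,
#' `fitted_support`, `v_high`, `v_low`, `n_points`, `seed`. Unknown
#' keys are ignored on read; missing optional keys become `NULL`/`NA`.
#'
#' @param path Path to the JSON file.
#' @return `read_calibration_json()`: a [pion_calibration()].
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("energy_label", "slope_m", "intercept_b")
  missing <- setdiff(need, names(j))
  if (length(missing)) {
    stop("calibration JSON missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  grab <- function(key, default) if (is.null(j[[key]])) default else j[[key]]
  pion_calibration(
    energy_label = j$energy_label,
    slope_m = j$slope_m, intercept_b = j$intercept_b,
    slope_interval = j$slope_interval,
    intercept_interval = j$intercept_interval,
    r_squared = grab("r_squared", NA_real_),
    fitted_support = grab("fitted_support", c(0, 120)),
    v_high = grab("v_high", 300), v_low = grab("v_low", 150),
    n_points = grab("n_points", NA_integer_),
    seed = grab("seed", NA_integer_)
  )
}

#' @param cal A [pion_calibration()].
#' @rdname read_calibration_json
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "pion_calibration"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Example Pion calibrations shipped with the package
#'
#' Returns one of three example calibrations (energy groups `"10FFF"`,
#' `"6FFF"`, `"6/10MV"`) stored as JSON fixtures under `extdata/`. The
#' higher-energy unflattened beam has roughly double the slope of the
#' lower-energy one, which in turn roughly doubles the pooled flattened
#' beams — recombination grows with dose per pulse. The fitted support
#' recorded in the fixtures is the package's evaluation window, [0, 120]
#' reference units.
#'
#' @param energy_label `"10FFF"`, `"6FFF"`, or `"6/10MV"`.
#' @return A [pion_calibration()].
#' @export
shipped_calibration <- function(energy_label = c("10FFF", "6FFF", "6/10MV")) {
  energy_label <- match.arg(energy_label)
  slug <- gsub("/", "-", tolower(energy_label), fixed = TRUE)
  path <- system.file("extdata", sprintf("calibration_%s.json", slug),
                      package = "pioncal", mustWork = TRUE)
  read_calibration_json(path)
}

#' Read a quality-conversion table from CSV
#'
#' Dialect: a `# chamber=<model>` metadata line, then a `pdd10,kq`
#' header and numeric rows with strictly increasing `pdd10`.
#'
#' @param path Path to the CSV file.
#' @return A [quality_conversion_table()].
#' @export
read_kq_table_csv <- function(path) {
  parsed <- .read_meta_csv(path)
  .require_meta(parsed$meta, "chamber", path)
  df <- .read_body(parsed$body, c("pdd10", "kq"))
  quality_conversion_table(parsed$meta[["chamber"]], df$pdd10, df$kq)
}

#' Read or write two-voltage measurement CSVs
#'
#' Dialect: optional `# key=value` metadata (e.g. `# energy=10FFF`),
#' then a `s_star_context,v_high,v_low,m_high,m_low` header and numeric
#' rows. `s_star_context` is the renormalized uncorrected signal at
#' which the reading pair was taken (the calibration abscissa).
#'
#' @param path Path to the CSV file.
#' @return `read_two_voltage_csv()`: a list with `readings` (data.frame)
#'   and `energy_label` (possibly empty).
#' @export
read_two_voltage_csv <- function(path) {
  parsed <- .read_meta_csv(path)
  df <- .read_body(parsed$body,
                   c("s_star_context", "v_high", "v_low", "m_high", "m_low"))
  # validates every row against the two-voltage preconditions
  compute_pion_two_voltage(df$m_high, df$m_low, df$v_high, df$v_low)
  list(readings = df,
       energy_label = if ("energy" %in% names(parsed$meta))
         parsed$meta[["energy"]] else "")
}

#' @param readings Data.frame with the five reading columns.
#' @param energy_label Optional energy metadata to record.
#' @rdname read_two_voltage_csv
#' @export
write_two_voltage_csv <- function(readings, path, energy_label = "") {
  need <- c("s_star_context", "v_high", "v_low", "m_high", "m_low")
  stopifnot(all(need %in% names(readings)))
  meta <- if (nzchar(energy_label)) sprintf("# energy=%s", energy_label)
          else character()
  rows <- do.call(paste, c(lapply(readings[need], .fmt_num), sep = ","))
  writeLines(c(meta, paste(need, collapse = ","), rows), path)
  invisible(path)
}

#' Read relative-dose-factor point readings from CSV
#'
#' Dialect: optional metadata lines, then a `field_cm,signal` header.
#'
#' @param path Path to the CSV file.
#' @return A list with `field_size`, `s_star`, and `energy_label`.
#' @export
read_rdf_csv <- function(path) {
  parsed <- .read_meta_csv(path)
  df <- .read_body(parsed$body, c("field_cm", "signal"))
  list(field_size = df$field_cm, s_star = df$signal,
       energy_label = if ("energy" %in% names(parsed$meta))
         parsed$meta[["energy"]] else "")
}
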