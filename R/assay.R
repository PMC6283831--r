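#' Fit a linear calibration curve
#'
#' Maps a blank-subtracted plate-reader signal to a known quantity. The
#' default fits through the origin (blank subtraction removes the offset),
#' with slope `sum(signal * quantity) / sum(signal^2)`; an intercept fit is
#' available for diagnostic comparison but the curve's applied slope is
#' always the signal coefficient.
#'
#' @param signal Blank-subtracted signals (absorbance or fluorescence).
#' @param quantity Known quantities (e.g. mg/L lycopene, g/L dry cell mass).
#' @param through_origin Fit without intercept (default)?
#' @param analyte Label, e.g. `"lycopene"` or `"dry_cell_mass"`.
#' @param wavelength Wavelength in nm (informational).
#' @return A `calibration_curve`: list with `slope` (quantity per signal
#'   unit), `analyte`, `wavelength`, `fit_points`, `replicate_slopes`.
#' @examples
#' fit_calibration(c(1, 2), c(2, 4), analyte = "lycopene")$slope  # 2
#' @export
fit_calibration <- function(signal, quantity, through_origin = TRUE,
                            analyte = "lycopene", wavelength = NA_real_) {
  stopifnot(length(signal) == length(quantity), length(signal) >= 2L)
  if (all(signal == 0)) stop("all signals are zero", call. = FALSE)
  slope <- if (through_origin) {
    sum(signal * quantity) / sum(signal^2)
  } else {
    unname(stats::coef(stats::lm(quantity ~ signal))[["signal"]])
  }
  if (slope <= 0) {
    stop("calibration slope is not positive; check signal/quantity pairing",
         call. = FALSE)
  }
  structure(list(slope = slope, analyte = analyte, wavelength = wavelength,
                 fit_points = data.frame(signal = signal, quantity = quantity),
                 replicate_slopes = NULL),
            class = "calibration_curve")
}

#' Construct a calibration curve from a known slope
#'
#' @param slope Quantity per signal unit (> 0).
#' @param analyte,wavelength As in [fit_calibration()].
#' @return A `calibration_curve`.
#' @export
calibration_curve <- function(slope, analyte = "lycopene",
                              wavelength = NA_real_) {
  stopifnot(slope > 0)
  structure(list(slope = slope, analyte = analyte, wavelength = wavelength,
                 fit_points = NULL, replicate_slopes = NULL),
            class = "calibration_curve")
}

#' Average replicate calibration curves
#'
#' Calibrations repeated on different occasions (e.g. months apart) are
#' combined by averaging their slopes; the component slopes are retained
#' for audit.
#'
#' @param ... Two or more `calibration_curve` objects for the same analyte.
#' @return A `calibration_curve` whose slope is the mean of the replicate
#'   slopes.
#' @export
average_calibrations <- function(...) {
  curves <- list(...)
  stopifnot(length(curves) >= 2L,
            all(vapply(curves, inherits, logical(1), "calibration_curve")))
  analytes <- unique(vapply(curves, `[[`, character(1), "analyte"))
  if (length(analytes) != 1L) {
    stop("cannot average curves for different analytes: ",
         paste(analytes, collapse = ", "), call. = FALSE)
  }
  slopes <- vapply(curves, `[[`, numeric(1), "slope")
  out <- curves[[1]]
  out$slope <- mean(slopes)
  out$replicate_slopes <- slopes
  out$fit_points <- NULL
  out
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s @%snm: slope %.6g%s\n",
              x$analyte, ifelse(is.na(x$wavelength), "?", x$wavelength),
              x$slope,
              if (!is.null(x$replicate_slopes)) {
                paste0(" (mean of ", length(x$replicate_slopes), " slopes)")
              } else ""))
  invisible(x)
}

#' Assemble plate measurements
#'
#' One row per run of blank-subtracted absorbances and the total dilution
#' factor applied between culture and measured well.
#'
#' @param run_id Run identifiers.
#' @param a475,a507 Blank-subtracted absorbances at the two lycopene peaks.
#' @param a600 Blank-subtracted absorbance at 600 nm (lycopene does not
#'   absorb there; used for contamination detection).
#' @param a700 Blank-subtracted absorbance at 700 nm (cell density).
#' @param dilution_factor Dilution factor(s), >= 1, recycled to length.
#' @param fluorescence Optional fluorescence signal (585/625 nm), arbitrary
#'   units, for fluorescent-protein titers.
#' @return A `plate_measurements` data frame.
#' @export
plate_measurements <- function(run_id, a475 = 0, a507 = 0, a600 = 0,
                               a700 = 0, dilution_factor = 1,
                               fluorescence = NA_real_) {
  n <- length(run_id)
  df <- data.frame(run_id = as.character(run_id),
                   a475 = rep_len(a475, n), a507 = rep_len(a507, n),
                   a600 = rep_len(a600, n), a700 = rep_len(a700, n),
                   dilution_factor = rep_len(dilution_factor, n),
                   fluorescence = rep_len(fluorescence, n),
                   stringsAsFactors = FALSE)
  if (any(df$dilution_factor < 1)) {
    stop("dilution_factor must be >= 1", call. = FALSE)
  }
  structure(df, class = c("plate_measurements", "data.frame"))
}

#' Total dilution factor of a serial dilution chain
#'
#' Each step takes an aliquot into a final volume; the total factor is the
#' product of `final / aliquot` over the steps. The standard growth assay
#' chain (250 uL culture diluted to 1250 uL, then 40 uL into a 200 uL
#' well) gives a factor of 25.
#'
#' @param steps A list of `c(aliquot, final)` volume pairs, or a 2-column
#'   matrix (aliquot, final), any consistent volume unit.
#' @return The total dilution factor.
#' @examples
#' dilution_chain(list(c(250, 1250), c(40, 200)))  # 25
#' @export
dilution_chain <- function(steps) {
  if (is.matrix(steps)) steps <- asplit(steps, 1)
  ratios <- vapply(steps, function(s) {
    stopifnot(length(s) == 2L, s[1] > 0, s[2] >= s[1])
    s[2] / s[1]
  }, numeric(1))
  prod(ratios)
}

# clamp negative blank-subtracted signals to zero (physical non-negativity)
clamp_signal <- function(x, what, tol = 0.005) {
  neg <- !is.na(x) & x < 0
  if (any(!is.na(x) & x < -tol)) {
    warning(sum(x < -tol, na.rm = TRUE), " ", what,
            " value(s) below -", tol, " clamped to 0", call. = FALSE)
  }
  x[neg] <- 0
  x
}

#' Lycopene titer from dual-wavelength absorbance
#'
#' Applies the two calibration slopes to the blank-subtracted absorbances
#' at 475 and 507 nm, averages the two single-wavelength estimates, and
#' scales by the dilution factor. Negative blank-subtracted absorbances
#' are clamped to zero (with a warning beyond tolerance).
#'
#' @param m A [plate_measurements()] table.
#' @param curve475,curve507 Calibration curves (mg/L per absorbance unit)
#'   at the two wavelengths.
#' @return Numeric vector of titers, mg/L.
#' @export
lycopene_titer <- function(m, curve475, curve507) {
  stopifnot(inherits(m, "plate_measurements"),
            inherits(curve475, "calibration_curve"),
            inherits(curve507, "calibration_curve"))
  a475 <- clamp_signal(m$a475, "A475")
  a507 <- clamp_signal(m$a507, "A507")
  (a475 * curve475$slope + a507 * curve507$slope) / 2 * m$dilution_factor
}

#' Dry cell mass from optical density at 700 nm
#'
#' @param m A [plate_measurements()] table.
#' @param od_curve Calibration curve, g/L dry cell mass per OD700 unit.
#' @return Numeric vector of dry cell masses, g/L.
#' @export
dry_cell_mass <- function(m, od_curve) {
  stopifnot(inherits(m, "plate_measurements"),
            inherits(od_curve, "calibration_curve"))
  clamp_signal(m$a700, "A700") * od_curve$slope * m$dilution_factor
}

#' Flag contaminated extract wells
#'
#' Lycopene does not absorb at 600 nm, so blank-subtracted absorbance
#' above a threshold there indicates contamination of the extract.
#'
#' @param m A [plate_measurements()] table.
#' @param threshold Absorbance threshold; see [blank_threshold()] for the
#'   limit-of-detection convention.
#' @return Logical vector.
#' @export
flag_contamination <- function(m, threshold) {
  stopifnot(inherits(m, "plate_measurements"), threshold >= 0)
  !is.na(m$a600) & m$a600 > threshold
}

#' Detection threshold from blank wells
#'
#' Standard limit-of-detection convention: `k` times the standard
#' deviation of the blank-well signals.
#'
#' @param blanks Blank-well signal values (>= 2).
#' @param k Multiplier (default 3).
#' @return Threshold value.
#' @export
blank_threshold <- function(blanks, k = 3) {
  stopifnot(length(blanks) >= 2L)
  k * stats::sd(blanks)
}

#' Assemble the three responses from plate measurements
#'
#' Converts raw measurements into the per-run response table: dry cell
#' mass (g/L), titer (mg/L or arbitrary fluorescence units) and yield
#' (titer / dry cell mass, the dimensionless per-biomass productivity).
#' Contaminated rows are flagged, never dropped; runs with zero dry cell
#' mass get a missing yield.
#'
#' @param m A [plate_measurements()] table.
#' @param curve475,curve507 Lycopene calibration curves.
#' @param od_curve Dry-cell-mass calibration curve.
#' @param contamination_threshold A600 threshold for [flag_contamination()].
#' @return A `response_table` data frame: `run_id`, `dry_cell_mass`,
#'   `titer`, `yield`, `contamination`.
#' @export
assemble_responses <- function(m, curve475, curve507, od_curve,
                               contamination_threshold = Inf) {
  dcm <- dry_cell_mass(m, od_curve)
  titer <- lycopene_titer(m, curve475, curve507)
  yield <- ifelse(dcm > 0, titer / dcm, NA_real_)
  response_table(data.frame(
    run_id = m$run_id, dry_cell_mass = dcm, titer = titer, yield = yield,
    contamination = flag_contamination(m, contamination_threshold),
    stringsAsFactors = FALSE))
}

#' Validate and class a response table
#'
#' @param df Data frame with columns `run_id`, `dry_cell_mass`, `titer`,
#'   `yield` (and optionally `contamination`).
#' @return A `response_table`.
#' @export
response_table <- function(df) {
  need <- c("run_id", "dry_cell_mass", "titer", "yield")
  stopifnot(all(need %in% names(df)))
  if (is.null(df$contamination)) df$contamination <- FALSE
  ok <- !is.na(df$yield) & df$dry_cell_mass > 0
  if (any(abs(df$yield[ok] * df$dry_cell_mass[ok] - df$titer[ok]) >
          1e-8 * pmax(1, abs(df$titer[ok])))) {
    stop("yield column is inconsistent with titer / dry_cell_mass",
         call. = FALSE)
  }
  structure(as.data.frame(df), class = c("response_table", "data.frame"))
}

#' Response column names of a response table
#' @param responses A `response_table`.
#' @return Character vector.
#' @export
response_names <- function(responses) {
  intersect(c("dry_cell_mass", "titer", "yield"), names(responses))
}
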