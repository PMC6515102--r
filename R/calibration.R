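#' Fit a linear calibration curve
#'
#' Ordinary (unweighted) least squares of detector response on concentration,
#' `response = slope * concentration + intercept`, as used for external
#' standard quantification. The fit quality is reported as the squared Pearson
#' correlation of response with concentration.
#'
#' @param concentration Numeric vector, mg/mL, at least two distinct values.
#' @param response Numeric vector of peak areas (detector units).
#' @param analyte Optional analyte name carried on the object.
#' @return An object of class `calibration_curve` with components `analyte`,
#'   `slope`, `intercept`, `r_squared`, `n_points` and `range`
#'   (min/max concentration).
#' @examples
#' cc <- fit_calibration(c(0, 1, 2), c(0, 5, 10))
#' coef(cc)
#' @export
fit_calibration <- function(concentration, response, analyte = "") {
  stopifnot(length(concentration) == length(response))
  if (length(concentration) < 2L)
    stop("need at least 2 calibration points")
  if (any(concentration < 0)) stop("concentrations must be >= 0")
  if (diff(range(concentration)) == 0)
    stop("all concentrations identical: singular fit")
  fit <- stats::lm(response ~ concentration)
  r2 <- if (stats::var(response) == 0) 1 else
    stats::cor(concentration, response)^2
  structure(list(analyte = analyte,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 n_points = length(concentration),
                 range = range(concentration)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, digits = 6, ...) {
  cat(sprintf("Calibration curve%s: Y = %s X %s %s  (r^2 = %s, n = %d)\n",
              if (nzchar(x$analyte)) paste0(" [", x$analyte, "]") else "",
              format(x$slope, digits = digits),
              if (x$intercept < 0) "-" else "+",
              format(abs(x$intercept), digits = digits),
              format(x$r_squared, digits = digits), x$n_points))
  cat(sprintf("  linear range: %g to %g mg/mL\n", x$range[1L], x$range[2L]))
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict detector response from concentration
#'
#' @param object A `calibration_curve`.
#' @param newdata Numeric vector of concentrations (mg/mL).
#' @param ... Unused.
#' @return Predicted peak areas.
#' @export
predict.calibration_curve <- function(object, newdata, ...) {
  object$slope * newdata + object$intercept
}

as_curve <- function(calib, analyte) {
  # row of a calibration_table -> calibration_curve
  i <- match(analyte, calib$analyte)
  if (is.na(i)) stop("no calibration curve for '", analyte, "'")
  structure(list(analyte = analyte, slope = calib$slope[i],
                 intercept = calib$intercept[i],
                 r_squared = calib$r_squared[i], n_points = NA_integer_,
                 range = c(calib$linear_low[i], calib$linear_high[i])),
            class = "calibration_curve")
}

#' Invert a calibration curve
#'
#' Converts a peak area back to a solution concentration,
#' `(area - intercept) / slope`. Results outside the curve's linear range are
#' returned (not rejected) with a range flag, since routine sample extracts
#' commonly fall outside the standards' validated range.
#'
#' @param curve A `calibration_curve` (or one row of a `calibration_table`
#'   via its analyte name and the table).
#' @param area Numeric vector of peak areas.
#' @return Numeric vector of concentrations (mg/mL) with attribute
#'   `range_flag`, a character vector in `"below"`, `"within"`, `"above"`.
#' @examples
#' cc <- fit_calibration(c(1, 2), c(18369.93, 37003.93)) # Y = 18634 X - 264.07
#' invert_calibration(cc, 1797.1)
#' @export
invert_calibration <- function(curve, area) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("zero slope: cannot invert")
  conc <- (area - curve$intercept) / curve$slope
  flag <- rep("within", length(conc))
  flag[conc < curve$range[1L]] <- "below"
  flag[conc > curve$range[2L]] <- "above"
  flag[is.na(conc)] <- NA_character_
  structure(conc, range_flag = flag)
}

#' Estimate LOD and LOQ from a dilution series
#'
#' The limit of detection is the lowest tested concentration whose
#' signal-to-noise ratio reaches 3:1; the limit of quantification the lowest
#' reaching 10:1 — the standard serial-dilution definition.
#'
#' @param concentration Numeric vector, mg/mL.
#' @param snr Numeric vector of signal-to-noise ratios, same length. The
#'   series is sorted by concentration internally; S/N is expected to be
#'   non-decreasing in concentration up to small inversions.
#' @return A list with elements `lod` and `loq` (mg/mL, or `NA` when no
#'   tested concentration reaches the threshold) and `determined` (logical).
#' @examples
#' estimate_lod_loq(c(0.04, 0.042, 0.139), c(2.9, 3.1, 10.2))
#' @export
estimate_lod_loq <- function(concentration, snr) {
  stopifnot(length(concentration) == length(snr))
  o <- order(concentration)
  concentration <- concentration[o]; snr <- snr[o]
  lod <- concentration[snr >= 3][1L]
  loq <- concentration[snr >= 10][1L]
  list(lod = lod, loq = loq,
       determined = c(lod = !is.na(lod), loq = !is.na(loq)))
}
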