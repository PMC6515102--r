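# Single-marker multi-component quantification (QAMS).
#
# The relative correction factor of analyte k against marker s is the slope
# ratio of their calibration curves, f_{k/s} = a_k / a_s. Sample content of a
# non-marker analyte then follows from its peak area and the marker's slope
# alone, C_k = A_k / (a_s * f_{k/s}). Two readings of the published content
# equation lead here: (i) taking the "A_s" symbol as the marker calibration
# slope gives C_k = A_k / (a_s f_k) directly; (ii) taking A_s as the marker's
# sample peak area, with the marker concentration obtained from a slope-only
# calibration C_s = A_s / a_s, gives C_k = C_s * A_k / (A_s f_k) =
# A_k / (a_s f_k) again. Both collapse to C_k = A_k / a_k: an intercept-free
# inversion of analyte k's own curve, which is exactly what makes a single
# affordable standard sufficient.

#' Relative correction factors from calibration slopes
#'
#' @param calib A `calibration_table` (see [read_calibration_table()]).
#' @param marker Name of the internal marker analyte.
#' @return An object of class `rcf_table`: a list with `marker` and
#'   `factors`, a named vector with `factors[marker] == 1` and all entries
#'   positive.
#' @examples
#' calib <- read_calibration_table(qams_fixture("calibration"))
#' compute_rcf(calib, "gastrodin")
#' @export
compute_rcf <- function(calib, marker) {
  stopifnot(inherits(calib, "calibration_table"))
  i <- match(marker, calib$analyte)
  if (is.na(i)) stop("marker '", marker, "' absent from calibration table")
  f <- calib$slope / calib$slope[i]
  names(f) <- calib$analyte
  f[marker] <- 1  # exact, not merely a ratio of equal floats
  structure(list(marker = marker, factors = f), class = "rcf_table")
}

#' @export
print.rcf_table <- function(x, ...) {
  cat("Relative correction factors (marker: ", x$marker, ")\n", sep = "")
  print(round(x$factors, 4))
  invisible(x)
}

#' Fit a single-marker quantification model
#'
#' Binds a calibration table to a chosen internal marker and precomputes the
#' relative correction factors. The returned model quantifies peak-area
#' tables by either the single-marker route (`predict(..., method="qams")`)
#' or the external standard route (`method="esm"`).
#'
#' @param calib A `calibration_table`.
#' @param marker Marker analyte name (default `"gastrodin"`).
#' @return An object of class `qams_model`.
#' @examples
#' calib <- read_calibration_table(qams_fixture("calibration"))
#' m <- qams(calib)
#' coef(m)
#' @export
qams <- function(calib, marker = "gastrodin") {
  rcf <- compute_rcf(calib, marker)
  structure(list(calibration = calib, marker = marker, rcf = rcf),
            class = "qams_model")
}

#' @export
print.qams_model <- function(x, ...) {
  cat("Single-marker quantification model\n")
  cat("  marker:", x$marker, "\n")
  cat("  analytes:", paste(x$calibration$analyte, collapse = ", "), "\n")
  cat("  relative correction factors:\n")
  print(round(x$rcf$factors, 4))
  invisible(x)
}

#' @export
coef.qams_model <- function(object, ...) object$rcf$factors

#' Quantify a peak table with a fitted single-marker model
#'
#' @param object A `qams_model`.
#' @param peaks A [peak_table()].
#' @param method `"qams"` (single-marker) or `"esm"` (external standard).
#' @param factor Extraction factor in mL/g (extract volume x dilution per g
#'   of dry material) converting solution concentration to content; see
#'   [quantify_qams()].
#' @param ... Unused.
#' @return A [content_table()].
#' @export
predict.qams_model <- function(object, peaks, method = c("qams", "esm"),
                               factor = 1, ...) {
  method <- match.arg(method)
  if (method == "qams")
    quantify_qams(peaks, object$rcf, object$calibration, factor = factor)
  else
    quantify_esm(peaks, object$calibration, factor = factor)
}

check_extraction_factor <- function(factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("extraction factor must be a single positive number (mL/g)")
  factor
}

#' Quantify by the external standard method
#'
#' Each analyte is quantified from its own calibration curve:
#' `content = (area - intercept) / slope * factor`, in mg per g of material.
#' Negative results (area below the intercept) are clipped to zero and
#' flagged `"below_zero"`; concentrations outside the curve's linear range
#' are flagged but kept.
#'
#' @param peaks A [peak_table()].
#' @param calib A `calibration_table` covering every analyte in `peaks`.
#' @param factor Extraction factor, mL/g. The published solvent-to-mass chain
#'   for this assay is ambiguous, so the factor is always explicit; the
#'   default 1 reports contents on the raw mg/mL solution scale.
#' @return A [content_table()] tagged `"esm"`.
#' @export
quantify_esm <- function(peaks, calib, factor = 1) {
  stopifnot(inherits(peaks, "peak_table"),
            inherits(calib, "calibration_table"))
  check_extraction_factor(factor)
  analytes <- colnames(peaks$areas)
  miss <- setdiff(analytes, calib$analyte)
  if (length(miss))
    stop("no calibration curve for: ", paste(miss, collapse = ", "))
  contents <- peaks$areas
  flags <- matrix(NA_character_, nrow(contents), ncol(contents),
                  dimnames = dimnames(contents))
  for (a in analytes) {
    cv <- as_curve(calib, a)
    conc <- invert_calibration(cv, peaks$areas[, a])
    flags[, a] <- attr(conc, "range_flag")
    val <- as.numeric(conc) * factor
    neg <- !is.na(val) & val < 0
    flags[neg, a] <- "below_zero"
    val[neg] <- 0
    contents[, a] <- val
  }
  content_table(contents, method = "esm", flags = flags, panel = peaks$panel)
}

#' Quantify by the single-marker method
#'
#' Non-marker analytes are quantified from the marker's calibration slope and
#' their relative correction factors,
#' `content = area / (a_s * f_k) * factor`, which needs no standard for
#' analyte k. The marker's own content is computed by the external standard
#' route (its full curve, intercept included), matching the usual reporting
#' convention of a single marker column; set `marker_by = "slope"` to force
#' the intercept-free slope-only inversion for the marker as well.
#'
#' @param peaks A [peak_table()].
#' @param rcf An `rcf_table` from [compute_rcf()].
#' @param calib A `calibration_table` containing at least the marker's curve.
#' @param factor Extraction factor, mL/g; see [quantify_esm()].
#' @param marker_by `"esm"` (default) or `"slope"`.
#' @return A [content_table()] tagged `"qams"`.
#' @export
quantify_qams <- function(peaks, rcf, calib, factor = 1,
                          marker_by = c("esm", "slope")) {
  stopifnot(inherits(peaks, "peak_table"), inherits(rcf, "rcf_table"),
            inherits(calib, "calibration_table"))
  marker_by <- match.arg(marker_by)
  check_extraction_factor(factor)
  analytes <- colnames(peaks$areas)
  miss <- setdiff(analytes, names(rcf$factors))
  if (length(miss))
    stop("analyte missing from RCF table: ", paste(miss, collapse = ", "))
  a_s <- calib$slope[match(rcf$marker, calib$analyte)]
  if (is.na(a_s)) stop("marker '", rcf$marker, "' has no calibration curve")
  contents <- sweep(peaks$areas, 2L,
                    a_s * rcf$factors[analytes], `/`) * factor
  flags <- matrix(NA_character_, nrow(contents), ncol(contents),
                  dimnames = dimnames(contents))
  if (rcf$marker %in% analytes && marker_by == "esm") {
    cv <- as_curve(calib, rcf$marker)
    conc <- invert_calibration(cv, peaks$areas[, rcf$marker])
    flags[, rcf$marker] <- attr(conc, "range_flag")
    val <- as.numeric(conc) * factor
    neg <- !is.na(val) & val < 0
    flags[neg, rcf$marker] <- "below_zero"
    val[neg] <- 0
    contents[, rcf$marker] <- val
  }
  content_table(contents, method = "qams", flags = flags,
                panel = peaks$panel)
}

#' Column means and row totals of a content table
#'
#' Reproduces the usual summary of a multi-batch content table: the
#' per-analyte mean content over all samples, and the per-sample total
#' content summed over the panel.
#'
#' @param table A [content_table()].
#' @return A list with `analyte_mean` (named vector, mg/g), `sample_total`
#'   (named vector, mg/g) and `total_mean` (mean of the sample totals).
#' @export
summarize_contents <- function(table) {
  stopifnot(inherits(table, "content_table"))
  analyte_mean <- colMeans(table$contents, na.rm = TRUE)
  sample_total <- rowSums(table$contents, na.rm = TRUE)
  list(analyte_mean = analyte_mean, sample_total = sample_total,
       total_mean = mean(sample_total))
}
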