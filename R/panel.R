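#' Define an analyte panel
#'
#' An analyte panel records the identities of the quantified compounds, their
#' elution order on the column, and which single analyte serves as the internal
#' marker (the one compound with an affordable reference standard, anchoring
#' all single-marker quantification).
#'
#' @param analytes Character vector of unique analyte names, given in elution
#'   order (first name elutes first).
#' @param marker Name of the marker analyte; must be one of `analytes`.
#' @return An object of class `analyte_panel`: a data.frame with columns
#'   `analyte`, `elution_order` and `role` (`"marker"` or `"target"`).
#' @examples
#' analyte_panel(c("gastrodin", "parishin_A"), marker = "gastrodin")
#' @export
analyte_panel <- function(analytes, marker) {
  analytes <- as.character(analytes)
  if (anyDuplicated(analytes))
    stop("analyte names must be unique")
  if (length(marker) != 1L || !marker %in% analytes)
    stop("'marker' must name exactly one analyte in the panel")
  panel <- data.frame(
    analyte = analytes,
    elution_order = seq_along(analytes),
    role = ifelse(analytes == marker, "marker", "target"),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("analyte_panel", "data.frame")
  panel
}

#' The seven-compound Gastrodia elata panel
#'
#' The standard panel for *Gastrodia elata* tuber extracts: gastrodin,
#' p-hydroxybenzyl alcohol, parishin E, p-hydroxy benzaldehyde, parishin B,
#' parishin C and parishin A, in elution order, with gastrodin as the internal
#' marker (chosen in practice for its availability, low cost, moderate
#' retention and stability).
#'
#' @return An `analyte_panel` with seven entries.
#' @examples
#' gastrodia_panel()
#' @export
gastrodia_panel <- function() {
  analyte_panel(
    c("gastrodin", "p_hydroxybenzyl_alcohol", "parishin_E",
      "p_hydroxy_benzaldehyde", "parishin_B", "parishin_C", "parishin_A"),
    marker = "gastrodin"
  )
}

marker_of <- function(panel) panel$analyte[panel$role == "marker"]

#' @export
print.analyte_panel <- function(x, ...) {
  cat("Analyte panel (", nrow(x), " analytes, marker: ",
      marker_of(x), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Construct a peak-area table
#'
#' A peak table is the sample-by-analyte matrix of chromatographic peak areas
#' (detector response units). Missing cells (peak not detected or not
#' integrated) are `NA`; they are never silently coerced to zero.
#'
#' @param areas Numeric matrix, one row per sample, one column per analyte.
#'   Column names must match the panel's analytes; row names are sample ids.
#' @param panel An [analyte_panel()]. Defaults to [gastrodia_panel()] when the
#'   columns match it.
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(areas, panel = NULL) {
  areas <- as.matrix(areas)
  if (is.null(rownames(areas)))
    rownames(areas) <- paste0("S", seq_len(nrow(areas)))
  if (is.null(colnames(areas)))
    stop("'areas' must have analyte column names")
  if (anyDuplicated(rownames(areas)))
    stop("duplicate sample id: ",
         rownames(areas)[duplicated(rownames(areas))][1L])
  if (is.null(panel)) {
    g <- gastrodia_panel()
    panel <- if (identical(colnames(areas), g$analyte)) g else
      analyte_panel(colnames(areas), marker = colnames(areas)[1L])
  }
  if (!identical(colnames(areas), panel$analyte))
    stop("column names must match the panel analytes, in elution order")
  bad <- which(!is.na(areas) & areas < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative peak area at [%s, %s]",
                 rownames(areas)[bad[1L, 1L]], colnames(areas)[bad[1L, 2L]]))
  structure(list(areas = areas, panel = panel), class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat("Peak table: ", nrow(x$areas), " samples x ", ncol(x$areas),
      " analytes (marker: ", marker_of(x$panel), ")\n", sep = "")
  print(utils::head(x$areas, 6))
  if (nrow(x$areas) > 6) cat("...\n")
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$areas)

#' Construct a content table
#'
#' Contents are expressed in mg per g of dry plant material and tagged with
#' the method that produced them: `"esm"` (external standard, per-analyte
#' calibration curve) or `"qams"` (single-marker with relative correction
#' factors).
#'
#' @param contents Numeric matrix (samples x analytes), mg/g. Negative values
#'   are not allowed; below-quantification cells should be 0 with a flag.
#' @param method `"esm"` or `"qams"`.
#' @param sd Optional matrix of per-cell standard deviations (same shape).
#' @param flags Optional character matrix of per-cell flags (e.g.
#'   `"below_zero"`, `"below_range"`).
#' @param panel Optional [analyte_panel()]; defaults as in [peak_table()].
#' @return An object of class `content_table`.
#' @export
content_table <- function(contents, method = c("esm", "qams"), sd = NULL,
                          flags = NULL, panel = NULL) {
  method <- match.arg(method)
  contents <- as.matrix(contents)
  if (is.null(colnames(contents)))
    stop("'contents' must have analyte column names")
  if (is.null(panel)) {
    g <- gastrodia_panel()
    panel <- if (all(colnames(contents) %in% g$analyte))
      analyte_panel(colnames(contents),
                    marker = if (marker_of(g) %in% colnames(contents))
                      marker_of(g) else colnames(contents)[1L])
    else analyte_panel(colnames(contents), marker = colnames(contents)[1L])
  }
  if (any(contents < 0, na.rm = TRUE))
    stop("contents must be >= 0 (clip below-zero results and flag them)")
  if (!is.null(sd)) stopifnot(identical(dim(sd), dim(contents)))
  structure(list(contents = contents, method = method, sd = sd,
                 flags = flags, panel = panel),
            class = "content_table")
}

#' @export
print.content_table <- function(x, ...) {
  cat("Content table [", toupper(x$method), "]: ", nrow(x$contents),
      " samples x ", ncol(x$contents), " analytes (mg/g)\n", sep = "")
  print(round(utils::head(x$contents, 6), 4))
  if (nrow(x$contents) > 6) cat("...\n")
  invisible(x)
}

#' Construct a chromatogram
#'
#' A uniformly sampled time/intensity trace. Input times must be strictly
#' increasing; traces whose spacing varies by more than 1e-6 min are resampled
#' onto a uniform grid by linear interpolation.
#'
#' @param time Numeric vector of retention times (minutes), strictly
#'   increasing.
#' @param intensity Numeric vector of detector response, same length.
#' @return An object of class `chromatogram` with elements `time`,
#'   `intensity` and `interval` (the uniform sampling interval, minutes).
#' @export
chromatogram <- function(time, intensity) {
  if (length(time) != length(intensity))
    stop("'time' and 'intensity' must have equal length")
  if (length(time) < 2L) stop("a chromatogram needs at least 2 points")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (diff(range(dt)) > 1e-6) {
    grid <- seq(time[1L], time[length(time)], length.out = length(time))
    intensity <- stats::approx(time, intensity, xout = grid)$y
    time <- grid
  }
  structure(list(time = time, intensity = intensity,
                 interval = (time[length(time)] - time[1L]) /
                   (length(time) - 1L)),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf(
    "Chromatogram: %d points, %.3f-%.3f min at %.4g min/point\n",
    length(x$time), x$time[1L], x$time[length(x$time)], x$interval))
  invisible(x)
}

#' @export
plot.chromatogram <- function(x, ...) {
  graphics::plot(x$time, x$intensity, type = "l",
                 xlab = "Retention time (min)",
                 ylab = "Intensity (detector units)", ...)
  invisible(x)
}
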