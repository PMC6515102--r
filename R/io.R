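# Delimited-text I/O. All tables are comma-separated UTF-8 with "." decimals
# and a header row; missing cells are empty fields, never 0.

#' Read a peak-area table
#'
#' The file must have a header row naming the analytes and a first column of
#' sample ids. Empty cells become `NA` (flagged missing).
#'
#' @param path Path to a CSV file.
#' @param panel Optional [analyte_panel()]; by default inferred from the
#'   header (the seven-compound Gastrodia panel when the header matches it).
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, panel = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("peak table needs a sample column plus analytes")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample id: ", ids[duplicated(ids)][1L])
  areas <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(areas) <- "double"
  rownames(areas) <- ids
  peak_table(areas, panel = panel)
}

#' Write a peak-area table
#'
#' @param x A [peak_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(x, path) {
  stopifnot(inherits(x, "peak_table"))
  df <- data.frame(sample = rownames(x$areas), x$areas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a calibration table
#'
#' Expects columns `analyte`, `slope`, `intercept`, `linear_low`,
#' `linear_high`, `r_squared`, `lod`, `loq`. Slopes are detector area per
#' mg/mL; ranges, LOD and LOQ are mg/mL.
#'
#' @param path Path to a CSV file.
#' @return A validated `calibration_table` data.frame.
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "slope", "intercept", "linear_low", "linear_high",
            "r_squared", "lod", "loq")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  calibration_table(df[need])
}

#' Validate a calibration table
#'
#' @param df A data.frame with the columns listed in
#'   [read_calibration_table()].
#' @return The validated data.frame with class `calibration_table`.
#' @export
calibration_table <- function(df) {
  if (anyDuplicated(df$analyte)) stop("duplicate analyte in calibration table")
  if (any(df$slope <= 0))
    stop("non-positive slope for ", df$analyte[df$slope <= 0][1L])
  if (any(df$linear_low >= df$linear_high))
    stop("linear range must satisfy low < high")
  if (any(df$lod > df$loq, na.rm = TRUE))
    stop("LOD > LOQ for ", df$analyte[which(df$lod > df$loq)][1L])
  if (any(df$r_squared < 0 | df$r_squared > 1))
    stop("r_squared must lie in [0, 1]")
  class(df) <- c("calibration_table", "data.frame")
  df
}

#' Write a calibration table
#'
#' @param x A `calibration_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calibration_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a content table
#'
#' Long CSV with columns `sample`, `analyte`, `method` (`esm`/`qams`),
#' `content` (mg/g) and optional `sd`. One method is extracted per call.
#'
#' @param path Path to a CSV file.
#' @param method Which method's rows to extract, `"esm"` or `"qams"`.
#' @return A [content_table()].
#' @export
read_content_table <- function(path, method = c("esm", "qams")) {
  method <- match.arg(method)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$method == method, , drop = FALSE]
  if (!nrow(df)) stop("no rows for method '", method, "'")
  samples <- unique(df$sample)
  analytes <- unique(df$analyte)
  m <- matrix(NA_real_, length(samples), length(analytes),
              dimnames = list(samples, analytes))
  s <- m
  m[cbind(match(df$sample, samples), match(df$analyte, analytes))] <- df$content
  if (!is.null(df$sd))
    s[cbind(match(df$sample, samples), match(df$analyte, analytes))] <- df$sd
  content_table(m, method = method, sd = if (!all(is.na(s))) s)
}

#' Write a content table (long format)
#'
#' @param x A [content_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_content_table <- function(x, path) {
  stopifnot(inherits(x, "content_table"))
  long <- expand.grid(sample = rownames(x$contents),
                      analyte = colnames(x$contents),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long <- long[order(match(long$sample, rownames(x$contents))), ]
  long$method <- x$method
  long$content <- x$contents[cbind(long$sample, long$analyte)]
  if (!is.null(x$sd)) long$sd <- x$sd[cbind(long$sample, long$analyte)]
  long <- long[!is.na(long$content), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a chromatogram
#'
#' Two numeric columns: time (minutes, strictly increasing) and intensity.
#' Non-uniform grids are resampled; see [chromatogram()].
#'
#' @param path Path to a 2-column CSV file (with header).
#' @return A [chromatogram()].
#' @export
read_chromatogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("chromatogram file needs two columns")
  chromatogram(as.numeric(df[[1L]]), as.numeric(df[[2L]]))
}

#' Write a chromatogram
#'
#' @param x A [chromatogram()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(x, path) {
  stopifnot(inherits(x, "chromatogram"))
  utils::write.csv(data.frame(time = x$time, intensity = x$intensity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Frozen md5 checksums of the packaged reference tables; filled in by
# fixture_checksums() during development and guarded by verify_fixtures().
.fixture_md5 <- c(
  table1_calibration.csv = "7ae1dcf56fb690a45f1a127a46adc3d6",
  table3_peak_areas.csv  = "1f21df65c171c84f6b69f9f316476aa7",
  table5_rcf_printed.csv = "209aca8387d8b4e486f6a65f3a91ec3b",
  table6_contents.csv    = "b84a71b165dd5fbed25f73dbe76d2e81",
  table8_provenance.csv  = "13a176d1c07f91e57f8ff61b4318b56a"
)

#' Path to a packaged reference table
#'
#' The package ships the published reference tables for the 21-batch
#' *Gastrodia elata* study as plain CSV fixtures: the calibration curves
#' (slopes, intercepts, linear ranges, LOD/LOQ), the 21 x 7 fingerprint
#' peak-area matrix, the printed relative correction factors, the ESM/QAMS
#' content tables and the sample provenance list. Values are transcribed
#' digit-for-digit as published, including apparent typos (e.g. one 0.00
#' QAMS content), so analyses see the data exactly as printed.
#'
#' @param name One of `"calibration"`, `"peak_areas"`, `"rcf_printed"`,
#'   `"contents"`, `"provenance"`.
#' @return Path to the installed CSV file.
#' @examples
#' read_peak_table(qams_fixture("peak_areas"))
#' @export
qams_fixture <- function(name = c("calibration", "peak_areas", "rcf_printed",
                                  "contents", "provenance")) {
  name <- match.arg(name)
  file <- switch(name,
    calibration = "table1_calibration.csv",
    peak_areas  = "table3_peak_areas.csv",
    rcf_printed = "table5_rcf_printed.csv",
    contents    = "table6_contents.csv",
    provenance  = "table8_provenance.csv")
  path <- system.file("extdata", file, package = "qamsr", mustWork = TRUE)
  path
}

#' Verify the packaged fixtures against their frozen checksums
#'
#' @return `TRUE` invisibly if all fixtures match; otherwise an error naming
#'   the corrupted file.
#' @export
verify_fixtures <- function() {
  for (file in names(.fixture_md5)) {
    path <- system.file("extdata", file, package = "qamsr", mustWork = TRUE)
    got <- unname(tools::md5sum(path))
    if (!identical(got, unname(.fixture_md5[[file]])))
      stop("fixture checksum mismatch for ", file)
  }
  invisible(TRUE)
}
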