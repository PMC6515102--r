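# Method-validation statistics: RSD, between-batch CV, spike recovery, and
# the ESM-vs-QAMS agreement report (relative error, pair RSD, Pearson r,
# paired t-test).

#' Relative standard deviation
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation — the universal
#' precision metric for replicate injections.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(1, 3)) # 70.71
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("zero mean: RSD undefined")
  100 * stats::sd(values) / m
}

#' Between-batch coefficient of variation per analyte
#'
#' The per-column CV (%) of a peak-area table, `100 * sd / mean` with the
#' sample standard deviation, measuring how strongly each component varies
#' across producing areas.
#'
#' @param peaks A [peak_table()] with at least two samples.
#' @return Named numeric vector of CVs in percent, one per analyte.
#' @export
cv_per_analyte <- function(peaks) {
  stopifnot(inherits(peaks, "peak_table"))
  if (nrow(peaks$areas) < 2L) stop("need at least 2 samples")
  apply(peaks$areas, 2L, function(x) {
    x <- x[!is.na(x)]
    if (all(x == 0)) stop("constant-zero column: CV undefined")
    100 * stats::sd(x) / mean(x)
  })
}

#' Spike recovery rate
#'
#' `(found - known) * 100 / added`, the accuracy metric for spiked samples.
#'
#' @param found Total amount found after spiking (mg).
#' @param known Amount known to be present before spiking (mg).
#' @param added Amount added (mg), > 0.
#' @return Recovery in percent.
#' @examples
#' recovery_rate(15, 10, 5) # 100
#' @export
recovery_rate <- function(found, known, added) {
  if (any(added <= 0)) stop("'added' must be positive")
  if (any(found < 0) || any(known < 0)) stop("amounts must be >= 0")
  (found - known) * 100 / added
}

#' Paired two-sided Student t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the differences `d = x - y`, with the
#' two-sided p-value evaluated through the regularized incomplete beta
#' function, `p = I_{df/(df+t^2)}(df/2, 1/2)`. Conventions for degenerate
#' input: all differences zero gives `t = 0, p = 1`; zero-variance nonzero
#' differences give infinite `t` and `p = 0`, flagged.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return List with `statistic`, `df`, `p_value` and `degenerate` (logical).
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  df <- n - 1
  if (all(d == 0))
    return(list(statistic = 0, df = df, p_value = 1, degenerate = TRUE))
  s <- stats::sd(d)
  if (s == 0)
    return(list(statistic = sign(mean(d)) * Inf, df = df, p_value = 0,
                degenerate = TRUE))
  t <- mean(d) / (s / sqrt(n))
  p <- stats::pbeta(df / (df + t^2), df / 2, 0.5)
  list(statistic = t, df = df, p_value = p, degenerate = FALSE)
}

#' Compare external-standard and single-marker content tables
#'
#' Per cell, the relative error `100 * |esm - qams| / mean(esm, qams)` and
#' the pair RSD `100 * sd(pair) / mean(pair)`; for two values these are tied
#' exactly by `relative_error = sqrt(2) * pair_rsd`. Per analyte (over
#' samples), the Pearson correlation of the two methods' contents and a
#' two-sided paired t-test. The marker analyte, which is quantified the same
#' way in both tables, is reported as not applicable; all-zero pairs are
#' flagged and excluded from the column statistics.
#'
#' @param esm A [content_table()] tagged `"esm"`.
#' @param qams A [content_table()] tagged `"qams"`. Sample sets must be
#'   identical; the comparison runs over the analytes present in both.
#' @return An object of class `agreement_report`: list with matrices
#'   `relative_error` and `pair_rsd` (percent), a per-analyte data.frame
#'   `by_analyte` (`pearson_r`, `t_statistic`, `p_value`, `n`), and
#'   `excluded` (all-zero pair positions).
#' @export
compare_methods <- function(esm, qams) {
  stopifnot(inherits(esm, "content_table"), inherits(qams, "content_table"))
  if (!identical(rownames(esm$contents), rownames(qams$contents)))
    stop("sample ids differ between the two tables")
  analytes <- intersect(colnames(esm$contents), colnames(qams$contents))
  if (!length(analytes)) stop("no analytes in common")
  samples <- rownames(esm$contents)
  E <- esm$contents[, analytes, drop = FALSE]
  Q <- qams$contents[, analytes, drop = FALSE]
  pm <- (E + Q) / 2
  zero <- !is.na(pm) & pm == 0
  re <- 100 * abs(E - Q) / pm
  prsd <- re / sqrt(2)              # exact for two-value pairs
  re[zero] <- NA_real_
  prsd[zero] <- NA_real_
  by <- do.call(rbind, lapply(analytes, function(a) {
    keep <- !zero[, a] & !is.na(E[, a]) & !is.na(Q[, a])
    x <- E[keep, a]; y <- Q[keep, a]
    r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      stats::cor(x, y)
    tt <- paired_ttest(x, y)
    data.frame(analyte = a, pearson_r = r, t_statistic = tt$statistic,
               p_value = tt$p_value, n = sum(keep),
               stringsAsFactors = FALSE)
  }))
  rownames(by) <- NULL
  structure(list(relative_error = re, pair_rsd = prsd, by_analyte = by,
                 excluded = which(zero, arr.ind = TRUE)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("ESM vs QAMS agreement over", nrow(x$relative_error), "samples\n")
  cat(sprintf("  max relative error: %.2f%%  max pair RSD: %.2f%%\n",
              max(x$relative_error, na.rm = TRUE),
              max(x$pair_rsd, na.rm = TRUE)))
  df <- x$by_analyte
  df$pearson_r <- round(df$pearson_r, 4)
  df$t_statistic <- round(df$t_statistic, 3)
  df$p_value <- round(df$p_value, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
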