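# Fingerprint stage: baseline noise estimation, peak detection/integration,
# consensus reference construction, multipoint retention-time correction and
# whole-trace similarity scoring.

#' Estimate baseline noise
#'
#' Robust spread of the detrended baseline: a straight line is fitted over
#' the stated quiet region and the median absolute deviation (scaled by
#' 1.4826 to estimate a Gaussian sd) of the residuals is returned. With no
#' region given, noise is estimated over the whole trace from first
#' differences, `mad(diff(y)) / sqrt(2)`, which is insensitive to peaks.
#'
#' @param chrom A [chromatogram()].
#' @param baseline_region Optional `c(t_start, t_end)` in minutes covering at
#'   least 20 samples and no peaks.
#' @return Noise standard deviation (detector units).
#' @export
estimate_noise <- function(chrom, baseline_region = NULL) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (is.null(baseline_region))
    return(stats::mad(diff(chrom$intensity)) / sqrt(2))
  idx <- which(chrom$time >= baseline_region[1L] &
               chrom$time <= baseline_region[2L])
  if (length(idx) < 20L)
    stop("baseline region must contain at least 20 samples")
  res <- stats::resid(stats::lm(chrom$intensity[idx] ~ chrom$time[idx]))
  stats::mad(res)
}

# Rolling-median baseline; window wide relative to peak widths.
.baseline <- function(y, interval, width_min = 2) {
  k <- max(3L, round(width_min / interval))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(y) %% 2L) length(y) else length(y) - 1L)
  stats::runmed(y, k, endrule = "median")
}

#' Detect and integrate chromatographic peaks
#'
#' Local maxima rising more than `min_snr` times the baseline noise above a
#' rolling-median baseline are kept as peak apices; peak bounds are placed at
#' the valley minima on either side, and the area is obtained by trapezoidal
#' integration above the straight line joining the bounds (valley-to-valley
#' local baseline).
#'
#' @param chrom A [chromatogram()].
#' @param min_snr Minimum apex signal-to-noise ratio (default 3).
#' @param min_width Minimum peak width at the valley bounds, minutes.
#' @param noise Optional known noise sd; estimated via [estimate_noise()]
#'   when `NULL`.
#' @return A data.frame with one row per peak: `apex_time`, `height`,
#'   `area`, `left`, `right`, `signal_to_noise`. Zero rows when no peak
#'   qualifies.
#' @export
detect_peaks <- function(chrom, min_snr = 3, min_width = 0.05, noise = NULL) {
  stopifnot(inherits(chrom, "chromatogram"))
  t <- chrom$time; y <- chrom$intensity; n <- length(y)
  if (is.null(noise)) noise <- estimate_noise(chrom)
  base <- .baseline(y, chrom$interval)
  above <- y - base
  # light smoothing for apex finding only; integration uses the raw trace
  k <- max(3L, round(min_width / chrom$interval / 2))
  if (k %% 2L == 0L) k <- k + 1L
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- as.numeric(ys)
  apex <- which(diff(sign(diff(ys))) < 0) + 1L
  thr <- if (noise > 0) min_snr * noise else
    .Machine$double.eps * max(abs(y), 1)
  apex <- apex[above[apex] > thr]
  if (!length(apex))
    return(data.frame(apex_time = numeric(), height = numeric(),
                      area = numeric(), left = numeric(), right = numeric(),
                      signal_to_noise = numeric()))
  out <- lapply(apex, function(i) {
    # refine apex to the raw-trace maximum near the smoothed apex
    lo <- max(1L, i - k); hi <- min(n, i + k)
    i <- lo + which.max(y[lo:hi]) - 1L
    l <- i; while (l > 1L && ys[l - 1L] < ys[l]) l <- l - 1L
    r <- i; while (r < n && ys[r + 1L] < ys[r]) r <- r + 1L
    if (t[r] - t[l] < min_width) return(NULL)
    total <- pracma::trapz(t[l:r], y[l:r])
    chord <- (y[l] + y[r]) / 2 * (t[r] - t[l])
    area <- total - chord
    if (area <= 0) return(NULL)
    h <- y[i] - base[i]
    data.frame(apex_time = t[i], height = h, area = area,
               left = t[l], right = t[r],
               signal_to_noise = if (noise > 0) h / noise else Inf)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(apex_time = numeric(),
                                      height = numeric(), area = numeric(),
                                      left = numeric(), right = numeric(),
                                      signal_to_noise = numeric())
  # duplicate apices from ripples within one valley pair: keep the highest
  out <- out[order(out$apex_time), , drop = FALSE]
  if (nrow(out) > 1L) {
    key <- paste(out$left, out$right)
    out <- do.call(rbind, lapply(split(out, key), function(d)
      d[which.max(d$height), , drop = FALSE]))
    out <- out[order(out$apex_time), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Build a consensus reference fingerprint
#'
#' Pointwise median (default, robust to single aberrant batches) or mean of
#' several chromatograms sharing a common time grid.
#'
#' @param chroms List of [chromatogram()]s on identical grids (align first).
#' @param method `"median"` or `"mean"`.
#' @return A [chromatogram()].
#' @export
build_reference <- function(chroms, method = c("median", "mean")) {
  method <- match.arg(method)
  if (length(chroms) < 2L) stop("need at least 2 chromatograms")
  t0 <- chroms[[1L]]$time
  for (c in chroms[-1L])
    if (length(c$time) != length(t0) || max(abs(c$time - t0)) > 1e-9)
      stop("chromatograms are not on a common time grid")
  Y <- do.call(rbind, lapply(chroms, `[[`, "intensity"))
  ref <- if (method == "median") apply(Y, 2L, stats::median) else colMeans(Y)
  chromatogram(t0, ref)
}

#' Align a chromatogram to a reference by multipoint correction
#'
#' Peaks are detected in both traces and matched greedily by nearest apex
#' within `window` minutes (closest pairs first, each apex used once, and
#' matches that would reorder peaks are dropped). Matched apices become
#' anchors of a piecewise-linear time warp; the retention-time offset is
#' interpolated linearly between anchors and tapers to zero at the trace
#' ends, so the warp is the identity outside the anchor span and never
#' reorders peaks. The warped trace is resampled onto the reference grid.
#'
#' @param chrom A [chromatogram()].
#' @param ref The reference [chromatogram()].
#' @param window Matching half-window in minutes (default 0.5).
#' @param min_snr Passed to [detect_peaks()].
#' @return A list with `chromatogram` (aligned trace), `map` (data.frame of
#'   anchors `observed_time`/`reference_time`) and `matched` (FALSE with a
#'   warning when no peaks matched; the trace is then returned unchanged).
#' @export
align_to_reference <- function(chrom, ref, window = 0.5, min_snr = 3) {
  stopifnot(inherits(chrom, "chromatogram"), inherits(ref, "chromatogram"))
  if (window <= 0) stop("'window' must be positive")
  pk <- detect_peaks(chrom, min_snr = min_snr)
  pr <- detect_peaks(ref, min_snr = min_snr)
  empty_map <- data.frame(observed_time = numeric(),
                          reference_time = numeric())
  if (!nrow(pk) || !nrow(pr)) {
    warning("no peaks to match; returning trace unchanged")
    return(list(chromatogram = chrom, map = empty_map, matched = FALSE))
  }
  d <- abs(outer(pk$apex_time, pr$apex_time, `-`))
  cand <- which(d <= window, arr.ind = TRUE)
  if (!nrow(cand)) {
    warning("no peak pairs within the matching window")
    return(list(chromatogram = chrom, map = empty_map, matched = FALSE))
  }
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_o <- logical(nrow(pk)); used_r <- logical(nrow(pr))
  anchors <- NULL
  for (i in seq_len(nrow(cand))) {
    o <- cand[i, 1L]; r <- cand[i, 2L]
    if (used_o[o] || used_r[r]) next
    used_o[o] <- TRUE; used_r[r] <- TRUE
    anchors <- rbind(anchors, c(pk$apex_time[o], pr$apex_time[r]))
  }
  anchors <- anchors[order(anchors[, 1L]), , drop = FALSE]
  keep <- c(TRUE, diff(anchors[, 2L]) > 0)  # enforce monotone warp
  anchors <- anchors[keep, , drop = FALSE]
  map <- data.frame(observed_time = anchors[, 1L],
                    reference_time = anchors[, 2L])
  # offset tapers to zero at the grid ends -> identity outside anchor span
  t <- chrom$time
  xs <- c(t[1L], map$observed_time, t[length(t)])
  off <- c(0, map$reference_time - map$observed_time, 0)
  o <- order(xs); xs <- xs[o]; off <- off[o]
  dup <- duplicated(xs); xs <- xs[!dup]; off <- off[!dup]
  warped <- t + stats::approx(xs, off, xout = t, rule = 2)$y
  y <- stats::approx(warped, chrom$intensity, xout = ref$time, rule = 2)$y
  list(chromatogram = chromatogram(ref$time, y), map = map, matched = TRUE)
}

#' Similarity between a chromatogram and a reference
#'
#' Whole-trace Pearson correlation (default) or cosine of the two intensity
#' vectors on a common grid. Pearson is invariant to intensity scaling and
#' baseline offsets; cosine to scaling only.
#'
#' @param chrom,ref [chromatogram()]s on identical grids (align first).
#' @param metric `"pearson"` or `"cosine"`.
#' @return Similarity in `[-1, 1]`; `NA` with a warning for a constant trace
#'   under the Pearson metric.
#' @export
similarity <- function(chrom, ref, metric = c("pearson", "cosine")) {
  metric <- match.arg(metric)
  stopifnot(inherits(chrom, "chromatogram"), inherits(ref, "chromatogram"))
  if (length(chrom$time) != length(ref$time) ||
      max(abs(chrom$time - ref$time)) > 1e-9)
    stop("traces are not on a common time grid; align first")
  x <- chrom$intensity; y <- ref$intensity
  if (metric == "pearson") {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("constant trace: Pearson similarity undefined")
      return(NA_real_)
    }
    stats::cor(x, y)
  } else {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) {
      warning("zero trace: cosine similarity undefined")
      return(NA_real_)
    }
    sum(x * y) / (nx * ny)
  }
}

#' Assemble a peak-area table from chromatograms
#'
#' Runs [detect_peaks()] on each trace and assigns detected peaks to panel
#' analytes by nearest apex within `window` minutes of the expected
#' retention times. Unmatched analytes become flagged-missing (`NA`) cells.
#'
#' @param chroms Named list of [chromatogram()]s (names become sample ids).
#' @param expected_rt Named numeric vector of expected apex times (minutes),
#'   names in elution order.
#' @param window Assignment half-window, minutes.
#' @param min_snr,min_width Passed to [detect_peaks()].
#' @param panel Optional [analyte_panel()] for the resulting table.
#' @return A [peak_table()].
#' @export
peak_table_from_chromatograms <- function(chroms, expected_rt, window = 0.5,
                                          min_snr = 3, min_width = 0.05,
                                          panel = NULL) {
  if (is.null(names(chroms)))
    names(chroms) <- paste0("S", seq_along(chroms))
  areas <- matrix(NA_real_, length(chroms), length(expected_rt),
                  dimnames = list(names(chroms), names(expected_rt)))
  for (s in names(chroms)) {
    pk <- detect_peaks(chroms[[s]], min_snr = min_snr, min_width = min_width)
    if (!nrow(pk)) next
    for (a in names(expected_rt)) {
      d <- abs(pk$apex_time - expected_rt[[a]])
      j <- which.min(d)
      if (d[j] <= window) areas[s, a] <- pk$area[j]
    }
  }
  peak_table(areas, panel = panel)
}
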