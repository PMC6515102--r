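# Synthetic chromatogram generator. No instrument data accompany the
# 21-batch study, so every pipeline stage is exercised on traces generated
# with the statistical structure the analysis assumes: exponentially
# modified Gaussian (EMG) peaks in the panel's elution order, lognormal
# between-batch concentration dispersion matching the published CVs,
# per-batch retention jitter, slow sinusoidal baseline drift and additive
# Gaussian detector noise.

# evaluate expr under a seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (has) assign(".Random.seed", old, envir = .GlobalEnv)
      else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    })
    set.seed(seed)
  }
  expr
}

# unit-area EMG density; tau = 0 degenerates to a pure Gaussian.
# Numerically stable via the scaled complementary error function where the
# plain erfc argument would overflow the leading exponential.
emg_density <- function(t, mu, sigma, tau) {
  if (tau <= 0) return(stats::dnorm(t, mu, sigma))
  z <- (sigma / tau - (t - mu) / sigma) / sqrt(2)
  out <- numeric(length(t))
  pos <- z >= 0
  out[pos] <- exp(-(t[pos] - mu)^2 / (2 * sigma^2)) *
    pracma::erfcx(z[pos]) / (2 * tau)
  out[!pos] <- exp(sigma^2 / (2 * tau^2) - (t[!pos] - mu) / tau) *
    pracma::erfc(z[!pos]) / (2 * tau)
  out
}

#' Specify a chromatographic peak
#'
#' @param analyte Analyte name.
#' @param retention_time Apex retention time of the Gaussian core, minutes.
#' @param sigma Gaussian width, minutes (> 0).
#' @param tau Exponential tail constant, minutes (0 = pure Gaussian).
#' @param response Detector response per concentration (area per mg/mL),
#'   i.e. the calibration slope the peak realizes.
#' @return A one-row data.frame of class `peak_spec`.
#' @export
peak_spec <- function(analyte, retention_time, sigma, tau = 0, response) {
  stopifnot(sigma > 0, tau >= 0, response > 0)
  structure(data.frame(analyte = analyte, retention_time = retention_time,
                       sigma = sigma, tau = tau, response = response,
                       stringsAsFactors = FALSE),
            class = c("peak_spec", "data.frame"))
}

#' Default seven-peak specification for the Gastrodia panel
#'
#' Retention times are spaced over the first half of the 130-min gradient in
#' the panel's elution order; detector responses equal the published
#' calibration slopes, so a generated peak's true area is `slope x conc` and
#' the generating concentrations are recoverable by either quantification
#' route.
#'
#' @param tau Common exponential-tail constant, minutes (default 0).
#' @return A `peak_spec` data.frame with seven rows.
#' @export
gastrodia_peak_specs <- function(tau = 0) {
  calib <- read_calibration_table(qams_fixture("calibration"))
  rt <- c(10.6, 16.8, 37.9, 47.2, 57.5, 61.8, 66.4)
  sg <- c(0.10, 0.10, 0.12, 0.10, 0.12, 0.12, 0.15)
  panel <- gastrodia_panel()
  specs <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    a <- panel$analyte[i]
    peak_spec(a, rt[i], sg[i], tau,
              calib$slope[match(a, calib$analyte)])
  }))
  class(specs) <- c("peak_spec", "data.frame")
  specs
}

#' Specify a multi-batch generation design
#'
#' Defaults emulate the 21-batch reference study: per-analyte mean
#' concentrations chosen so mean peak areas match the published fingerprint
#' table, between-batch CVs equal to its printed CV row (32-97%), modest
#' retention jitter, and low detector noise relative to peak heights.
#'
#' @param n_batches Number of batches (>= 2; default 21).
#' @param mean_conc Named vector of mean concentrations, mg/mL. Default:
#'   published mean areas divided by the calibration slopes.
#' @param cv Named vector of between-batch CVs in percent. Default: the
#'   published CV row.
#' @param rt_jitter_sd Per-batch retention-time jitter sd, minutes
#'   (default 0.1, keeping typical shifts within the 0.5-min matching
#'   window).
#' @param noise_sd Additive Gaussian noise sd, detector units.
#' @param drift_amplitude Amplitude of the slow sinusoidal baseline drift.
#' @param seed Integer seed; all randomness of a panel flows from it.
#' @return A list of class `batch_spec`.
#' @export
batch_spec <- function(n_batches = 21, mean_conc = NULL, cv = NULL,
                       rt_jitter_sd = 0.1, noise_sd = 0.5,
                       drift_amplitude = 2, seed = 1) {
  if (n_batches < 2L) stop("need at least 2 batches")
  if (is.null(mean_conc) || is.null(cv)) {
    pk <- read_peak_table(qams_fixture("peak_areas"))
    calib <- read_calibration_table(qams_fixture("calibration"))
    slopes <- calib$slope[match(colnames(pk$areas), calib$analyte)]
    if (is.null(mean_conc))
      mean_conc <- stats::setNames(colMeans(pk$areas) / slopes,
                                   colnames(pk$areas))
    if (is.null(cv)) cv <- cv_per_analyte(pk)
  }
  stopifnot(all(mean_conc > 0), all(cv >= 0), rt_jitter_sd >= 0,
            noise_sd >= 0)
  structure(list(n_batches = as.integer(n_batches), mean_conc = mean_conc,
                 cv = cv, rt_jitter_sd = rt_jitter_sd, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude, seed = seed),
            class = "batch_spec")
}

#' Render a synthetic chromatogram
#'
#' The trace is the sum of EMG peaks (analyte k contributes exact area
#' `response_k x conc_k`), a slow sinusoidal baseline drift, and additive
#' Gaussian noise. Identical seeds give bit-identical traces.
#'
#' @param specs A `peak_spec` data.frame (one row per peak).
#' @param conc Named vector of concentrations, mg/mL, covering all analytes
#'   in `specs`.
#' @param grid `c(t_start, t_end, interval)` in minutes; must cover every
#'   retention time by at least 5 widths. An interval coarser than
#'   `sigma / 3` triggers a warning (attribute `grid_warning`).
#' @param noise_sd Gaussian noise sd, detector units.
#' @param drift_amplitude Drift amplitude, detector units.
#' @param seed Optional integer seed (caller RNG state is preserved).
#' @return A [chromatogram()].
#' @export
make_chromatogram <- function(specs, conc, grid = c(0, 130, 0.01),
                              noise_sd = 0, drift_amplitude = 0,
                              seed = NULL) {
  stopifnot(inherits(specs, "data.frame"))
  lo <- min(specs$retention_time - 5 * specs$sigma)
  hi <- max(specs$retention_time + 5 * (specs$sigma + specs$tau))
  if (grid[1L] > lo || grid[2L] < hi)
    stop("grid must cover all retention times by at least 5 widths")
  warn <- any(grid[3L] > specs$sigma / 3)
  if (warn) warning("grid interval coarser than sigma/3: peaks undersampled")
  t <- seq(grid[1L], grid[2L], by = grid[3L])
  y <- numeric(length(t))
  for (i in seq_len(nrow(specs))) {
    a <- specs$analyte[i]
    if (!a %in% names(conc)) stop("no concentration for ", a)
    area <- specs$response[i] * conc[[a]]
    y <- y + area * emg_density(t, specs$retention_time[i], specs$sigma[i],
                                specs$tau[i])
  }
  if (drift_amplitude != 0)
    y <- y + drift_amplitude * sin(2 * pi * t / (diff(range(t)) / 3))
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  out <- chromatogram(t, y)
  attr(out, "grid_warning") <- warn
  out
}

#' Generate a noisy calibration series
#'
#' Areas follow `response x conc x (1 + eps)` with
#' `eps ~ Normal(0, noise_fraction)`; the signal-to-noise field is the
#' peak's apex height over `noise_sd` under the peak-shape model.
#'
#' @param spec A single-row `peak_spec`.
#' @param concs Positive, distinct concentrations, mg/mL.
#' @param noise_fraction Relative area noise (0 = exact linearity).
#' @param noise_sd Detector noise sd used for the S/N field.
#' @param seed Optional integer seed.
#' @return A data.frame with `concentration`, `response` (area) and
#'   `signal_to_noise`.
#' @export
make_calibration_series <- function(spec, concs, noise_fraction = 0,
                                    noise_sd = 1, seed = NULL) {
  stopifnot(nrow(spec) == 1L, all(concs > 0), !anyDuplicated(concs))
  eps <- if (noise_fraction > 0)
    with_seed(seed, stats::rnorm(length(concs), 0, noise_fraction))
  else numeric(length(concs))
  area <- spec$response * concs * (1 + eps)
  apex <- max(emg_density(seq(spec$retention_time - 5 * spec$sigma,
                              spec$retention_time + 5 * (spec$sigma + spec$tau),
                              length.out = 2001L),
                          spec$retention_time, spec$sigma, spec$tau))
  data.frame(concentration = concs, response = area,
             signal_to_noise = area * apex / noise_sd)
}

#' Generate a multi-batch panel of chromatograms
#'
#' Batch concentrations are drawn lognormally around the stated means with
#' the stated CVs (`sdlog = sqrt(log(1 + cv^2))`, so areas stay positive
#' even at CVs near 100%); each batch receives one Normal retention shift
#' applied to all its peaks, emulating run-to-run drift. Both the true
#' peak-area table (`response x conc`, before rendering) and the rendered
#' traces are returned.
#'
#' @param batch A [batch_spec()].
#' @param specs A `peak_spec` data.frame; defaults to
#'   [gastrodia_peak_specs()].
#' @param grid Passed to [make_chromatogram()].
#' @return A list with `peak_table` (the generating truth), `chromatograms`
#'   (named list), and `concentrations` (batches x analytes matrix, mg/mL).
#' @export
make_panel <- function(batch, specs = gastrodia_peak_specs(),
                       grid = c(0, 130, 0.01)) {
  stopifnot(inherits(batch, "batch_spec"))
  analytes <- specs$analyte
  mean_conc <- batch$mean_conc[analytes]
  cv <- batch$cv[analytes] / 100
  if (anyNA(mean_conc) || anyNA(cv))
    stop("batch spec must provide mean_conc and cv for every analyte")
  ids <- paste0("S", seq_len(batch$n_batches))
  with_seed(batch$seed, {
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(mean_conc) - sdlog^2 / 2
    conc <- sapply(seq_along(analytes), function(j)
      stats::rlnorm(batch$n_batches, meanlog[j], sdlog[j]))
    dimnames(conc) <- list(ids, analytes)
    shifts <- stats::rnorm(batch$n_batches, 0, batch$rt_jitter_sd)
    noise_seeds <- sample.int(.Machine$integer.max, batch$n_batches)
    chroms <- lapply(seq_len(batch$n_batches), function(i) {
      sp <- specs
      sp$retention_time <- sp$retention_time + shifts[i]
      make_chromatogram(sp, stats::setNames(conc[i, ], analytes),
                        grid = grid,
                        noise_sd = batch$noise_sd,
                        drift_amplitude = batch$drift_amplitude,
                        seed = noise_seeds[i])
    })
    names(chroms) <- ids
    areas <- sweep(conc, 2L, specs$response, `*`)
    list(peak_table = peak_table(areas), chromatograms = chroms,
         concentrations = conc)
  })
}
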