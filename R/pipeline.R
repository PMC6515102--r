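# End-to-end orchestration: one call reproduces every published number the
# packaged fixtures support, and one call runs the full pipeline on
# generated data.

#' Reproduce the published tables from the packaged fixtures
#'
#' Verifies the fixture checksums, then recomputes: the relative correction
#' factors from the calibration slopes (against the printed values), the
#' between-batch CV row of the fingerprint peak-area table, the content-table
#' column means and row totals, and the full ESM-vs-QAMS agreement report.
#' A pass/fail manifest compares each recomputed quantity with its printed
#' counterpart at printed precision.
#'
#' @param factor Extraction factor (mL/g) used when quantifying the raw
#'   peak-area fixture; the published solvent/mass chain is ambiguous, so
#'   absolute published contents are not targeted and the default 1 keeps
#'   the mg/mL solution scale.
#' @return A list of class `run_report` with components `rcf`, `cv`,
#'   `content_summary`, `agreement`, `contents_from_areas` and `manifest`.
#' @export
run_reproduction <- function(factor = 1) {
  verify_fixtures()
  calib <- read_calibration_table(qams_fixture("calibration"))
  peaks <- read_peak_table(qams_fixture("peak_areas"))
  printed_rcf <- utils::read.csv(qams_fixture("rcf_printed"),
                                 stringsAsFactors = FALSE)
  esm <- read_content_table(qams_fixture("contents"), "esm")
  qm <- read_content_table(qams_fixture("contents"), "qams")

  model <- qams(calib, marker = "gastrodin")
  rcf <- data.frame(analyte = printed_rcf$analyte,
                    computed = unname(coef(model)[printed_rcf$analyte]),
                    printed = printed_rcf$rcf_printed)
  rcf$diff <- rcf$computed - rcf$printed

  cv <- cv_per_analyte(peaks)
  sums <- summarize_contents(esm)
  agreement <- compare_methods(esm, qm)
  contents_from_areas <- predict(model, peaks, method = "qams",
                                 factor = factor)

  manifest <- data.frame(
    check = c("rcf_p_hydroxybenzyl_alcohol", "rcf_parishin_E",
              "rcf_p_hydroxy_benzaldehyde", "rcf_parishin_A",
              "cv_gastrodin", "cv_min",
              "content_mean_gastrodin", "content_total_mean",
              "content_total_S1", "content_total_S19"),
    value = c(rcf$computed[match(c("p_hydroxybenzyl_alcohol", "parishin_E",
                                   "p_hydroxy_benzaldehyde", "parishin_A"),
                                 rcf$analyte)],
              cv[["gastrodin"]], min(cv),
              sums$analyte_mean[["gastrodin"]], sums$total_mean,
              sums$sample_total[["S1"]], sums$sample_total[["S19"]]),
    printed = c(2.1090, 0.7589, 2.8194, 0.6316, 49.7, 32.2,
                3.53, 20.70, 27.68, 5.76),
    digits = c(4, 4, 4, 4, 1, 1, 2, 2, 2, 2))
  manifest$pass <- round(manifest$value, manifest$digits) == manifest$printed

  structure(list(rcf = rcf, cv = cv, content_summary = sums,
                 agreement = agreement,
                 contents_from_areas = contents_from_areas,
                 manifest = manifest),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline report\n")
  if (!is.null(x$manifest)) {
    cat("Reproduction manifest:\n")
    m <- x$manifest
    m$value <- signif(m$value, 6)
    print(m, row.names = FALSE)
  }
  if (!is.null(x$similarities)) {
    cat(sprintf("Similarities: min %.4f over %d batches\n",
                min(x$similarities), length(x$similarities)))
  }
  invisible(x)
}

#' Configuration for a synthetic pipeline run
#'
#' @param seed Integer seed governing all randomness of the run.
#' @param n_batches Number of generated batches.
#' @param window Retention-time matching half-window, minutes.
#' @param metric Similarity metric, `"pearson"` or `"cosine"`.
#' @param k Number of groups for the cluster cut.
#' @param linkage Linkage for [hca()].
#' @param factor Extraction factor, mL/g.
#' @param grid Time grid `c(start, end, interval)`, minutes.
#' @param rt_jitter_sd,noise_sd,drift_amplitude Generator settings; see
#'   [batch_spec()].
#' @return A list of class `run_config`.
#' @export
synthetic_config <- function(seed = 1, n_batches = 21, window = 0.5,
                             metric = c("pearson", "cosine"), k = 3,
                             linkage = "ward", factor = 1,
                             grid = c(0, 75, 0.01), rt_jitter_sd = 0.1,
                             noise_sd = 0.5, drift_amplitude = 2) {
  metric <- match.arg(metric)
  if (window <= 0) stop("'window' must be > 0")
  if (k < 1) stop("'k' must be >= 1")
  structure(list(seed = seed, n_batches = n_batches, window = window,
                 metric = metric, k = k, linkage = linkage, factor = factor,
                 grid = grid, rt_jitter_sd = rt_jitter_sd,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude),
            class = "run_config")
}

#' Run the full pipeline on generated data
#'
#' Generates a multi-batch panel, detects and integrates peaks on the
#' rendered traces, quantifies them by both the external standard and the
#' single-marker route, compares the two, aligns every batch to the median
#' consensus fingerprint and scores its similarity, and clusters the
#' standardized true peak areas. Deterministic for a given seed.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `run_report` with components `panel`,
#'   `detected`, `contents_esm`, `contents_qams`, `agreement`,
#'   `similarities`, `clusters` and `config`.
#' @export
run_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "run_config"))
  calib <- read_calibration_table(qams_fixture("calibration"))
  specs <- gastrodia_peak_specs()
  batch <- batch_spec(n_batches = config$n_batches,
                      rt_jitter_sd = config$rt_jitter_sd,
                      noise_sd = config$noise_sd,
                      drift_amplitude = config$drift_amplitude,
                      seed = config$seed)
  panel <- make_panel(batch, specs, grid = config$grid)

  rt <- stats::setNames(specs$retention_time, specs$analyte)
  detected <- peak_table_from_chromatograms(panel$chromatograms, rt,
                                            window = config$window)
  model <- qams(calib, marker = "gastrodin")
  esm <- predict(model, detected, method = "esm", factor = config$factor)
  qm <- predict(model, detected, method = "qams", factor = config$factor)
  agreement <- compare_methods(esm, qm)

  ref <- build_reference(panel$chromatograms, method = "median")
  sims <- vapply(panel$chromatograms, function(ch) {
    al <- align_to_reference(ch, ref, window = config$window)
    similarity(al$chromatogram, ref, metric = config$metric)
  }, numeric(1))

  z <- standardize(panel$peak_table)
  clusters <- cut_tree(hca(z, linkage = config$linkage), k = config$k)

  structure(list(panel = panel, detected = detected, contents_esm = esm,
                 contents_qams = qm, agreement = agreement,
                 similarities = sims, clusters = clusters, config = config),
            class = "run_report")
}
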