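# shared helpers for building small in-code fixtures

fixture_calibration <- function() {
  read_calibration_table(qams_fixture("calibration"))
}

fixture_peaks <- function() {
  read_peak_table(qams_fixture("peak_areas"))
}

fixture_contents <- function(method) {
  read_content_table(qams_fixture("contents"), method)
}

# one noiseless Gaussian peak on a trimmed grid
gaussian_trace <- function(height = 100, mu = 5, sigma = 0.05,
                           interval = 0.005, span = 2) {
  t <- seq(mu - span, mu + span, by = interval)
  chromatogram(t, height * exp(-(t - mu)^2 / (2 * sigma^2)))
}

# single-analyte peak spec for fast generator tests
tiny_spec <- function(response = 1000, rt = 5, sigma = 0.08, tau = 0) {
  peak_spec("x", rt, sigma, tau, response)
}
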