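# Noise estimation, peak detection/integration, reference construction,
# retention-time correction and similarity.

test_that("baseline noise is recovered from a known-sigma region", {
  set.seed(11)
  t <- seq(0, 100, by = 0.01)
  ch <- chromatogram(t, rnorm(length(t), 0, 1))
  est <- estimate_noise(ch, c(0, 100))
  expect_gt(est, 0.95); expect_lt(est, 1.05)

  flat <- chromatogram(t[1:100], rep(3, 100))
  expect_equal(estimate_noise(flat, range(flat$time)), 0)
  drift <- chromatogram(t[1:100], 2 + 0.5 * t[1:100])
  expect_equal(estimate_noise(drift, range(drift$time)), 0, tolerance = 1e-12)
  expect_error(estimate_noise(flat, c(0, 0.05)), "at least 20")
})

test_that("a noiseless Gaussian integrates to height * sigma * sqrt(2 pi)", {
  for (interval in c(0.01, 0.002)) {
    ch <- gaussian_trace(height = 100, sigma = 0.05, interval = interval)
    pk <- detect_peaks(ch, min_width = 0.02)
    expect_equal(nrow(pk), 1L)
    truth <- 100 * 0.05 * sqrt(2 * pi)
    expect_lt(abs(pk$area - truth) / truth, 0.01)
    expect_equal(pk$apex_time, 5, tolerance = 2 * interval)
    expect_true(pk$left < pk$apex_time && pk$apex_time < pk$right)
  }
})

test_that("flat traces yield no peaks", {
  t <- seq(0, 10, by = 0.01)
  expect_equal(nrow(detect_peaks(chromatogram(t, rep(1, length(t))))), 0L)
})

test_that("baseline-resolved peak pairs are detected as exactly two", {
  # resolution Rs = dt / (4 sigma) = 1.75 > 1.5
  t <- seq(0, 10, by = 0.005)
  y <- 100 * exp(-(t - 4)^2 / (2 * 0.1^2)) +
       60 * exp(-(t - 4.7)^2 / (2 * 0.1^2))
  pk <- detect_peaks(chromatogram(t, y), min_width = 0.02)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$apex_time, c(4, 4.7), tolerance = 0.01)
})

test_that("the consensus reference is the pointwise median or mean", {
  ch <- gaussian_trace()
  out <- build_reference(list(ch, ch, ch), "median")
  expect_equal(out$intensity, ch$intensity)

  bad <- chromatogram(ch$time, ch$intensity * 10)
  rob <- build_reference(list(ch, ch, ch, ch, bad), "median")
  expect_equal(rob$intensity, ch$intensity)

  two <- build_reference(list(ch, bad), "mean")
  expect_equal(two$intensity, (ch$intensity + bad$intensity) / 2)
  shifted <- chromatogram(ch$time + 1, ch$intensity)
  expect_error(build_reference(list(ch, shifted)), "common time grid")
})

test_that("alignment corrects a uniform shift within one sampling interval", {
  t <- seq(0, 20, by = 0.01)
  peaks_at <- function(mu) Reduce(`+`, lapply(mu, function(m)
    100 * exp(-(t - m)^2 / (2 * 0.08^2))))
  ref <- chromatogram(t, peaks_at(c(5, 9, 14)))
  obs <- chromatogram(t, peaks_at(c(5, 9, 14) + 0.3))
  al <- align_to_reference(obs, ref, window = 0.5)
  expect_true(al$matched)
  expect_equal(nrow(al$map), 3L)
  apex <- detect_peaks(al$chromatogram, min_width = 0.02)$apex_time
  expect_equal(apex, c(5, 9, 14), tolerance = 0.011)
  expect_gt(similarity(al$chromatogram, ref), 0.99)
})

test_that("aligning a trace to itself is the identity", {
  ch <- gaussian_trace()
  al <- align_to_reference(ch, ch)
  expect_true(al$matched)
  expect_equal(al$map$observed_time, al$map$reference_time)
  expect_equal(al$chromatogram$intensity, ch$intensity, tolerance = 1e-10)
})

test_that("shifts beyond the window produce no matches and a warning", {
  t <- seq(0, 20, by = 0.01)
  ref <- chromatogram(t, 100 * exp(-(t - 5)^2 / (2 * 0.08^2)))
  obs <- chromatogram(t, 100 * exp(-(t - 5.8)^2 / (2 * 0.08^2)))
  expect_warning(al <- align_to_reference(obs, ref, window = 0.5),
                 "window")
  expect_false(al$matched)
  expect_equal(al$chromatogram$intensity, obs$intensity)
  expect_equal(nrow(al$map), 0L)
})

test_that("alignment never reorders peaks", {
  t <- seq(0, 20, by = 0.01)
  mk <- function(mu) chromatogram(t, Reduce(`+`, lapply(mu, function(m)
    100 * exp(-(t - m)^2 / (2 * 0.08^2)))))
  ref <- mk(c(4, 8, 12, 16))
  set.seed(3)
  for (i in 1:5) {
    obs <- mk(c(4, 8, 12, 16) + rnorm(4, 0, 0.15))
    al <- align_to_reference(obs, ref)
    expect_true(all(diff(al$map$observed_time) > 0))
    expect_true(all(diff(al$map$reference_time) > 0))
  }
})

test_that("similarity is symmetric and respects metric invariances", {
  ch <- gaussian_trace()
  expect_equal(similarity(ch, ch), 1)
  other <- chromatogram(ch$time, ch$intensity + rnorm(length(ch$time), 0, 5))
  expect_equal(similarity(ch, other), similarity(other, ch))
  scaled <- chromatogram(ch$time, 7 * ch$intensity + 3)
  expect_equal(similarity(ch, scaled), 1, tolerance = 1e-12)
  expect_equal(similarity(ch, chromatogram(ch$time, 7 * ch$intensity),
                          metric = "cosine"), 1, tolerance = 1e-12)

  # non-overlapping peaks on a zero baseline are orthogonal under cosine
  t <- seq(0, 10, by = 0.01)
  a <- chromatogram(t, 100 * exp(-(t - 2)^2 / (2 * 0.05^2)))
  b <- chromatogram(t, 100 * exp(-(t - 8)^2 / (2 * 0.05^2)))
  expect_lt(abs(similarity(a, b, metric = "cosine")), 1e-6)

  flat <- chromatogram(t, rep(1, length(t)))
  expect_warning(s <- similarity(flat, a), "constant")
  expect_true(is.na(s))
})

test_that("peak tables assembled from traces map analytes by retention", {
  sp <- gastrodia_peak_specs()[1:3, ]
  conc <- c(gastrodin = 0.1, p_hydroxybenzyl_alcohol = 0.05,
            parishin_E = 0.15)
  ch <- make_chromatogram(sp, conc, grid = c(5, 45, 0.01))
  rt <- setNames(sp$retention_time, sp$analyte)
  pt <- peak_table_from_chromatograms(list(B1 = ch), rt)
  truth <- sp$response * conc[sp$analyte]
  expect_equal(unname(pt$areas["B1", ]), unname(truth), tolerance = 0.01)
})
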