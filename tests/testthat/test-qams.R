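# Relative correction factors and the two quantification routes.

test_that("relative correction factors are the published slope ratios", {
  model <- qams(fixture_calibration(), marker = "gastrodin")
  f <- coef(model)
  expect_identical(unname(f["gastrodin"]), 1)
  expect_equal(unname(round(f["p_hydroxybenzyl_alcohol"], 4)), 2.1090)
  expect_equal(unname(round(f["parishin_A"], 4)), 0.6316)
  expect_equal(unname(f["p_hydroxybenzyl_alcohol"]), 39300 / 18634)
  expect_true(all(f > 0))
})

test_that("RCFs are invariant to rescaling every slope", {
  calib <- fixture_calibration()
  scaled <- as.data.frame(calib)
  scaled$slope <- scaled$slope * 3.7
  f1 <- compute_rcf(calib, "gastrodin")$factors
  f2 <- compute_rcf(calibration_table(scaled), "gastrodin")$factors
  expect_equal(f1, f2)
  expect_error(compute_rcf(calib, "nope"), "absent")
})

test_that("ESM quantification inverts each analyte's own curve", {
  calib <- fixture_calibration()
  # forward-inverse identity at 0.25 mg/mL for the marker
  a <- 18634 * 0.25 - 264.07
  pk <- peak_table(matrix(a, 1, 1, dimnames = list("A", "gastrodin")))
  ct <- quantify_esm(pk, calib, factor = 1)
  expect_equal(unname(ct$contents[1L, 1L]), 0.25)

  # published S1 gastrodin area -> hand-computed concentration
  pk2 <- peak_table(matrix(1797.1, 1, 1,
                           dimnames = list("S1", "gastrodin")))
  ct2 <- quantify_esm(pk2, calib)
  expect_equal(unname(ct2$contents[1L, 1L]), (1797.1 + 264.07) / 18634)

  # area below the intercept clips to zero with a flag
  pkb <- peak_table(matrix(10, 1, 1,
                           dimnames = list("A", "p_hydroxybenzyl_alcohol")))
  ctb <- quantify_esm(pkb, calib)
  expect_equal(unname(ctb$contents[1L, 1L]), 0)
  expect_identical(unname(ctb$flags[1L, 1L]), "below_zero")

  # missing curve is a hard error; missing area propagates as missing
  pkx <- peak_table(matrix(1, 1, 1, dimnames = list("A", "unknown")))
  expect_error(quantify_esm(pkx, calib), "no calibration curve")
  pkm <- peak_table(matrix(c(NA, 100), 2, 1,
                           dimnames = list(c("A", "B"), "gastrodin")))
  ctm <- quantify_esm(pkm, calib)
  expect_true(is.na(ctm$contents["A", 1L]))
})

test_that("single-marker quantification is the intercept-free inversion", {
  calib <- fixture_calibration()
  rcf <- compute_rcf(calib, "gastrodin")

  # f = 2, a_s = 10, A = 40 -> 2.0, via a synthetic two-analyte system
  cal2 <- calibration_table(data.frame(
    analyte = c("s", "k"), slope = c(10, 20), intercept = c(0, 0),
    linear_low = c(0, 0), linear_high = c(10, 10),
    r_squared = c(1, 1), lod = c(0, 0), loq = c(0, 0)))
  rcf2 <- compute_rcf(cal2, "s")
  pk <- peak_table(matrix(c(5, 40), 1, 2, dimnames = list("A", c("s", "k"))))
  ct <- quantify_qams(pk, rcf2, cal2)
  expect_equal(unname(ct$contents[1L, "k"]), 2)

  # published S1 parishin A area over its slope
  pk2 <- peak_table(matrix(4340.3, 1, 1, dimnames = list("S1", "parishin_A")))
  expect_error(quantify_qams(pk2, compute_rcf(cal2, "s"), cal2), "missing")
  ct2 <- quantify_qams(pk2, rcf, calib)
  expect_equal(unname(ct2$contents[1L, 1L]), 4340.3 / 11769)  # 0.36879
})

test_that("QAMS minus ESM equals the intercept term exactly", {
  calib <- fixture_calibration()
  rcf <- compute_rcf(calib, "gastrodin")
  pk <- fixture_peaks()
  for (factor in c(1, 25 / 2)) {
    esm <- quantify_esm(pk, calib, factor = factor)
    qm <- quantify_qams(pk, rcf, calib, factor = factor)
    for (a in setdiff(colnames(pk$areas), "gastrodin")) {
      b_over_a <- calib$intercept[calib$analyte == a] /
        calib$slope[calib$analyte == a]
      clipped <- esm$flags[, a] %in% "below_zero"
      gap <- (qm$contents[!clipped, a] - esm$contents[!clipped, a])
      expect_equal(unname(gap), rep(b_over_a * factor, sum(!clipped)),
                   tolerance = 1e-12)
    }
    # marker column reported by ESM in both tables
    expect_equal(qm$contents[, "gastrodin"], esm$contents[, "gastrodin"])
  }
})

test_that("QAMS contents are linear in peak areas", {
  calib <- fixture_calibration()
  rcf <- compute_rcf(calib, "gastrodin")
  pk <- fixture_peaks()
  q1 <- quantify_qams(pk, rcf, calib, marker_by = "slope")
  q2 <- quantify_qams(peak_table(pk$areas * 2), rcf, calib,
                      marker_by = "slope")
  expect_equal(q2$contents, q1$contents * 2)
})

test_that("zero intercepts make the two routes identical everywhere", {
  calib <- as.data.frame(fixture_calibration())
  calib$intercept <- 0
  calib <- calibration_table(calib)
  rcf <- compute_rcf(calib, "gastrodin")
  pk <- fixture_peaks()
  esm <- quantify_esm(pk, calib)
  qm <- quantify_qams(pk, rcf, calib)
  expect_equal(qm$contents, esm$contents, tolerance = 1e-12)
})

test_that("content summaries reproduce the published means and totals", {
  esm <- fixture_contents("esm")
  s <- summarize_contents(esm)
  expect_equal(round(unname(s$analyte_mean["gastrodin"]), 2), 3.53)
  expect_equal(unname(s$sample_total["S1"]), 27.68)
  expect_equal(round(s$total_mean, 2), 20.70)

  one <- content_table(matrix(c(1, 2, 4), 1, 3,
                              dimnames = list("A", c("x", "y", "z"))),
                       method = "esm")
  s1 <- summarize_contents(one)
  expect_equal(unname(s1$sample_total), 7)
  expect_equal(s1$total_mean, 7)
})
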