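# RSD/CV/recovery and the ESM-vs-QAMS agreement statistics.

test_that("RSD uses the sample standard deviation over the mean", {
  expect_equal(rsd(c(2, 2, 2)), 0)
  expect_equal(rsd(c(1, 3)), 100 * sqrt(2) / 2)  # 70.71
  expect_equal(round(rsd(c(3.54, 3.60)), 2), 1.19)
  expect_error(rsd(c(-1, 1)), "zero mean")
  expect_error(rsd(2), "at least 2")
})

test_that("between-batch CVs reproduce the published dispersion row", {
  cv <- cv_per_analyte(fixture_peaks())
  expect_equal(round(unname(cv["gastrodin"]), 1), 49.7)
  expect_equal(round(min(cv), 1), 32.2)
  printed <- c(gastrodin = 49.7, p_hydroxybenzyl_alcohol = 85.2,
               parishin_E = 33.3, p_hydroxy_benzaldehyde = 96.5,
               parishin_B = 32.2, parishin_C = 50.1, parishin_A = 47.9)
  expect_true(all(abs(cv[names(printed)] - printed) < 0.1))

  const <- peak_table(matrix(c(5, 5, 1, 2), 2, 2,
                             dimnames = list(NULL, c("a", "b"))))
  expect_equal(unname(cv_per_analyte(const)["a"]), 0)
  zero <- peak_table(matrix(0, 2, 1, dimnames = list(NULL, "a")))
  expect_error(cv_per_analyte(zero), "constant-zero")
})

test_that("recovery rate is (found - known) * 100 / added", {
  expect_equal(recovery_rate(15, 10, 5), 100)
  expect_equal(recovery_rate(14.6, 10, 5), 92)
  expect_equal(recovery_rate(10, 10, 5), 0)
  expect_error(recovery_rate(10, 10, 0), "positive")
})

test_that("paired t-test matches the closed form and the t-CDF oracle", {
  res <- paired_ttest(c(1, 2, 4), c(1.1, 2.2, 3.9))
  expect_equal(round(res$statistic, 4), -0.7559)
  # independent oracle for the p-value: Student t CDF via stats::pt
  expect_lt(abs(res$p_value - 2 * stats::pt(-abs(res$statistic), res$df)),
            1e-9)
})

test_that("paired t-test agrees with t.test on random inputs", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    x <- rnorm(n, 5, 2)
    y <- x + rnorm(n, 0.1, 0.5)
    mine <- paired_ttest(x, y)
    ref <- stats::t.test(x, y, paired = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("paired t-test conventions and antisymmetry hold", {
  x <- c(1, 2, 3)
  same <- paired_ttest(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  shift <- paired_ttest(x + 1, x)  # zero-variance nonzero differences
  expect_identical(shift$statistic, Inf)
  expect_equal(shift$p_value, 0)

  a <- c(1, 2, 4); b <- c(1.1, 2.2, 3.9)
  ab <- paired_ttest(a, b); ba <- paired_ttest(b, a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("relative error is sqrt(2) times the pair RSD, exactly", {
  esm <- fixture_contents("esm")
  qm <- fixture_contents("qams")
  rep <- compare_methods(esm, qm)
  ok <- !is.na(rep$relative_error)
  expect_equal(rep$relative_error[ok], sqrt(2) * rep$pair_rsd[ok],
               tolerance = 1e-15)
  # spot value: the S1 parishin B pair
  expect_equal(round(rep$relative_error["S1", "parishin_B"], 2), 1.68)
  expect_equal(round(rep$pair_rsd["S1", "parishin_B"], 2), 1.19)
})

test_that("method agreement on the published contents is tight", {
  rep <- compare_methods(fixture_contents("esm"), fixture_contents("qams"))
  by <- rep$by_analyte
  expect_setequal(by$analyte,
                  setdiff(gastrodia_panel()$analyte, "gastrodin"))
  # five of six analytes correlate above 0.999 even from 2 d.p. contents
  expect_gte(sort(by$pearson_r, decreasing = TRUE)[5L], 0.999)
  expect_true(all(by$p_value >= 0 & by$p_value <= 1))
  expect_true(all(abs(by$pearson_r) <= 1))
})

test_that("identical tables give zero errors and the p = 1 convention", {
  ct <- fixture_contents("qams")
  rep <- compare_methods(ct, ct)
  expect_true(all(rep$relative_error == 0 | is.na(rep$relative_error)))
  expect_true(all(rep$by_analyte$p_value == 1))
  # constant columns are flagged undefined rather than faked
  cA <- content_table(matrix(c(1, 1, 2, 3), 2, 2,
                             dimnames = list(c("A", "B"), c("x", "y"))),
                      "esm")
  rep2 <- compare_methods(cA, content_table(cA$contents, "qams"))
  expect_true(is.na(rep2$by_analyte$pearson_r[rep2$by_analyte$analyte == "x"]))
})

test_that("all-zero pairs are excluded from column statistics", {
  E <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("A", "B", "C"), "x"))
  Q <- matrix(c(0, 1.1, 1.9), 3, 1, dimnames = list(c("A", "B", "C"), "x"))
  rep <- compare_methods(content_table(E, "esm"), content_table(Q, "qams"))
  expect_equal(nrow(rep$excluded), 1L)
  expect_equal(rep$by_analyte$n, 2L)
  expect_true(is.na(rep$relative_error["A", "x"]))
})
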