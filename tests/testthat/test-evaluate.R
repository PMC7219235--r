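# Metrics, Bland-Altman, AAMI, BHS, attention sections, report round trip.

test_that("regression metrics handle exact, constant and alternating errors", {
  y <- c(100, 110, 120, 130)
  m <- regression_metrics(y, y)
  expect_equal(unlist(m[c("rmse", "mae", "sd_abs_err")]),
               c(rmse = 0, mae = 0, sd_abs_err = 0))
  expect_equal(m$r2, 1)
  # constant predictor at the mean: R2 = 0
  m2 <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(m2$r2, 0)
  # errors (+3, -3, +3, -3): rmse = mae = 3, sd of |e| = 0
  m3 <- regression_metrics(y, y + c(3, -3, 3, -3))
  expect_equal(m3$rmse, 3)
  expect_equal(m3$mae, 3)
  expect_equal(m3$sd_abs_err, 0)
  expect_true(m3$rmse >= m3$mae)
  expect_error(regression_metrics(rep(5, 4), y), "zero-variance")
})

test_that("Bland-Altman limits follow mean +/- 1.96 SD and translate", {
  y <- c(100, 110, 120, 130)
  ba <- bland_altman(y, y)
  expect_equal(unlist(ba), c(mean_diff = 0, loa_low = 0, loa_high = 0))
  set.seed(2)
  yh <- y + rnorm(4)
  ba1 <- bland_altman(y, yh)
  ba2 <- bland_altman(y, yh + 3)
  expect_equal(ba2$mean_diff, ba1$mean_diff + 3)
  expect_equal(ba2$loa_low, ba1$loa_low + 3)
  expect_equal(ba2$loa_high, ba1$loa_high + 3)
  # width invariant
  d <- yh - y
  expect_equal(ba1$loa_high - ba1$loa_low, 2 * 1.96 * stats::sd(d),
               tolerance = 1e-9)
})

test_that("Bland-Altman LOA reproduce the sigma = 4.85 construction", {
  set.seed(99)
  n <- 1e5
  y <- rnorm(n, 110, 10)
  yh <- y + rnorm(n, 0, 4.85)
  ba <- bland_altman(y, yh)
  expect_equal(ba$loa_high, 9.50, tolerance = 0.15 / 9.50)
  expect_equal(ba$loa_low, -9.50, tolerance = 0.15 / 9.50)
})

test_that("AAMI verdict applies inclusive mean/SD limits", {
  y <- seq(100, 130, length.out = 50)
  a0 <- aami_check(y, y)
  expect_true(a0$pass)
  expect_equal(a0$mean_error, 0)
  expect_equal(a0$sd_error, 0)
  # constant +6 error: mean over the limit, SD zero -> fail
  a6 <- aami_check(y, y + 6)
  expect_false(a6$pass)
  # symmetric errors with sample SD exactly 8 pass on the boundary
  n <- 50
  e <- rep(c(1, -1), n / 2) * 8 * sqrt((n - 1) / n)
  ab <- aami_check(y, y + e)
  expect_equal(ab$sd_error, 8, tolerance = 1e-12)
  expect_true(ab$pass)
  # nudging the SD just over the limit fails
  expect_false(aami_check(y, y + e * 1.01)$pass)
  # subject-count sufficiency is a flag, not a failure
  expect_false(aami_check(y, y, n_subjects = 15)$n_subjects_sufficient)
  expect_true(aami_check(y, y, n_subjects = 85)$n_subjects_sufficient)
})

test_that("BHS grading matches the cumulative thresholds", {
  y <- rep(100, 100)
  g0 <- bhs_grade(y, y)
  expect_equal(g0$grade, "A")
  expect_equal(c(g0$p5, g0$p10, g0$p15), c(100, 100, 100))
  # constructed coverage (73, 93, 98) -> A
  e <- c(rep(0, 73), rep(7, 20), rep(12, 5), rep(20, 2))
  gA <- bhs_grade(y, y + e)
  expect_equal(c(gA$p5, gA$p10, gA$p15), c(73, 93, 98))
  expect_equal(gA$grade, "A")
  # constructed coverage (55, 80, 92) -> B (fails A at 80 < 85)
  e2 <- c(rep(0, 55), rep(7, 25), rep(12, 12), rep(20, 8))
  gB <- bhs_grade(y, y + e2)
  expect_equal(c(gB$p5, gB$p10, gB$p15), c(55, 80, 92))
  expect_equal(gB$grade, "B")
  # monotonicity: shrinking |e| never worsens the grade
  rank_of <- function(g) match(g, c("D", "C", "B", "A"))
  set.seed(5)
  for (i in 1:25) {
    err <- rnorm(60, 0, runif(1, 2, 15))
    g1 <- bhs_grade(y[1:60], y[1:60] + err)
    g2 <- bhs_grade(y[1:60], y[1:60] + 0.5 * err)
    expect_gte(rank_of(g2$grade), rank_of(g1$grade))
  }
})

test_that("attention sections reproduce the 81-sample timing arithmetic", {
  set.seed(8)
  A <- matrix(runif(10 * 8), 10)
  A <- A / rowSums(A)
  sec <- attention_sections(A)
  expect_equal(nrow(sec), 8)
  expect_equal(sec$duration_ms[1:7], rep(648, 7))
  expect_equal(sec$duration_ms[8], 464)
  expect_equal(sec$time_to_end_s[6], 1.112)
  expect_equal(sec$time_to_end_s[2], 3.704)
  expect_equal(sec$time_to_end_s[8], 0)
  expect_equal(sec$mean_weight, colMeans(A))
  expect_equal(sum(sec$end_sample[8]), 625)
  expect_error(attention_sections(matrix(1, 2, 5)), "inconsistent")
})

test_that("evaluation reports serialize losslessly through JSON", {
  set.seed(3)
  y_s <- rnorm(200, 115, 12); y_d <- rnorm(200, 70, 8)
  rep0 <- eval_report(y_s, y_s + rnorm(200, 0, 4),
                      y_d, y_d + rnorm(200, 0, 3),
                      n_subjects = 3, label = "demo")
  # internal consistency
  expect_gte(rep0$sbp$rmse, rep0$sbp$mae)
  expect_lte(rep0$sbp$bhs$p5, rep0$sbp$bhs$p10)
  expect_lte(rep0$sbp$bhs$p10, rep0$sbp$bhs$p15)
  path <- file.path(withr::local_tempdir(), "report.json")
  write_eval_report(rep0, path)
  rep1 <- read_eval_report(path)
  expect_equal(rep1$sbp$rmse, rep0$sbp$rmse, tolerance = 1e-12)
  expect_equal(rep1$dbp$bland_altman$loa_low, rep0$dbp$bland_altman$loa_low,
               tolerance = 1e-12)
  expect_equal(rep1$sbp$bhs$grade, rep0$sbp$bhs$grade)
  expect_equal(rep1$dbp$aami$pass, rep0$dbp$aami$pass)
})
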