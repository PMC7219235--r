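# Fiducial detection and the MLR comparator.

baseline_fixture <- function() {
  cache_get("baseline_fix", function() {
    cfg <- synth_config(duration_s = 60, hr_mean = 60, hr_sd = 0.5, seed = 4)
    out <- generate_recording(cfg)
    out$filtered <- filter_recording(out$recording)
    out
  })
}

test_that("Pan-Tompkins finds clean 60 bpm beats within 10 ms", {
  fx <- baseline_fixture()
  r <- detect_r_peaks(fx$filtered$channels$ecg, fx$filtered$fs)
  expect_lte(abs(length(r) - 60), 1)
  err <- vapply(r, function(x) min(abs(fx$truth$r_times - x)), numeric(1))
  expect_lt(max(err), 0.010)
  expect_true(all(diff(r) > 0))
})

test_that("R detection ignores amplitude scaling and flat signals", {
  fx <- baseline_fixture()
  r <- detect_r_peaks(fx$filtered$channels$ecg, fx$filtered$fs)
  r10 <- detect_r_peaks(fx$filtered$channels$ecg * 10, fx$filtered$fs)
  expect_identical(r, r10)
  expect_warning(r0 <- detect_r_peaks(rep(0, 5000), 1000), "no R peaks")
  expect_length(r0, 0)
})

test_that("J peaks are found at the planted RJI and edge cycles are invalid", {
  out <- generate_recording(clean_synth_config(duration_s = 30, seed = 2,
                                               rji_sd = 10))
  rec <- filter_recording(out$recording)
  tr <- out$truth
  j <- detect_j_peaks(rec$channels$bcg, rec$fs, tr$r_times)
  expect_equal(nrow(j), length(tr$r_times))
  valid <- which(j$valid)
  expect_gt(length(valid), length(tr$r_times) - 3)
  expect_lt(max(abs(j$time[valid] - tr$j_times[valid])), 0.004)
  # a window that runs past the end of the signal flags the cycle invalid
  j2 <- detect_j_peaks(rec$channels$bcg, rec$fs,
                       r_times = length(rec$channels$bcg) / rec$fs - 0.15)
  expect_false(j2$valid[1])
})

test_that("a J wave planted outside the search window is rejected", {
  # construct a BCG whose 'J' sits 300 ms after each R: the 110-250 ms
  # window sees only a rising edge, so the argmax hugs the boundary
  fs <- 1000
  r_times <- seq(0.5, 19.5, by = 1)
  t <- (0:(20 * fs - 1)) / fs
  bcg <- numeric(length(t))
  for (r in r_times) {
    idx <- which(t >= r + 0.22 & t <= r + 0.38)
    u <- t[idx] - (r + 0.300)
    bcg[idx] <- bcg[idx] + (1 - (u / 0.02)^2) * exp(-u^2 / (2 * 0.02^2))
  }
  j <- detect_j_peaks(bcg, fs, r_times)
  expect_true(all(!j$valid))
  expect_true(all(is.na(j$time) | j$time - r_times <= 0.250))
})

test_that("dPPG peaks recover planted PTT and equivariance under time shift", {
  # clean (noise-free) PPG at constant planted PTT 250 ms: the derivative
  # peak must land at onset + template offset within 8 ms
  fz <- generate_recording(frozen_synth_config(duration_s = 30, seed = 7))
  dpf <- detect_dppg_peaks(fz$recording$channels$ppg, fz$recording$fs,
                           fz$truth$r_times)
  expect_gt(sum(dpf$valid), 20)
  err_f <- (dpf$time - fz$truth$ppg_dpeak_times)[dpf$valid]
  expect_lt(max(abs(err_f)), 0.008)
  expect_equal(mean(dpf$time[dpf$valid] - fz$truth$r_times[dpf$valid]),
               0.250 + ppg_dpeak_offset(), tolerance = 0.004)
  # modulated-PTT clean cohort for equivariance / validity flags
  out <- generate_recording(clean_synth_config(duration_s = 30, seed = 7))
  rec <- out$recording
  tr <- out$truth
  dp <- detect_dppg_peaks(rec$channels$ppg, rec$fs, tr$r_times)
  valid <- which(dp$valid)
  expect_gt(length(valid), 20)
  # uniform +20 ms shift of the whole channel moves every PTT by 20 ms
  k <- round(0.020 * rec$fs)
  ppg_shift <- c(rep(rec$channels$ppg[1], k),
                 rec$channels$ppg[1:(length(rec$channels$ppg) - k)])
  dp2 <- detect_dppg_peaks(ppg_shift, rec$fs, tr$r_times)
  both <- dp$valid & dp2$valid
  expect_lt(max(abs((dp2$time - dp$time)[both] - 0.020)), 0.002)
  # a cycle whose PPG is flattened to zero (incl. the smoothing margin)
  # has no positive derivative maximum and is flagged invalid
  ppg0 <- rec$channels$ppg
  r3 <- tr$r_times[3]
  ppg0[round((r3 - 0.05) * rec$fs):round((r3 + 0.7) * rec$fs)] <- 0
  dp3 <- detect_dppg_peaks(ppg0, rec$fs, tr$r_times)
  expect_false(dp3$valid[3])
})

test_that("feature rows subtract times and report the exclusion fraction", {
  r <- c(1.0, 1.8, 2.6, 3.4)
  j <- data.frame(time = r + 0.18, valid = c(TRUE, TRUE, TRUE, TRUE))
  dppg <- data.frame(time = r + 0.25, valid = c(TRUE, TRUE, FALSE, TRUE))
  f <- build_features(r, j, dppg)
  # 3 cycles between 4 R peaks; the third has a missing dPPG
  expect_equal(nrow(f), 2)
  expect_equal(f$ptt, c(0.25, 0.25))
  expect_equal(f$rri[1], 0.8)
  expect_equal(f$rji, c(0.18, 0.18))
  expect_equal(attr(f, "excluded_frac"), 1 / 3)
  # 100 cycles with 21 missing fiducials -> 79 rows, 21% excluded
  set.seed(21)
  r100 <- seq(1, by = 0.8, length.out = 101)  # 101 R peaks = 100 cycles
  ok <- rep(TRUE, 101)
  ok[sample(1:100, 21)] <- FALSE
  j100 <- data.frame(time = r100 + 0.18, valid = ok)
  d100 <- data.frame(time = r100 + 0.3, valid = TRUE)
  f100 <- build_features(r100, j100, d100)
  expect_equal(nrow(f100), 79)
  expect_equal(attr(f100, "excluded_frac"), 0.21)
  expect_error(build_features(r, j, data.frame(time = r, valid = FALSE)),
               "zero valid")
})

test_that("OLS recovers the planted coupling exactly on noiseless features", {
  out <- generate_recording(clean_synth_config(duration_s = 120, seed = 5))
  ft <- features_from_truth(out$truth)
  m <- fit_mlr(ft)
  cf <- coef(m)
  # planted: sbp = 165 - 0.2 * ptt_ms; features in seconds -> coef / 1000
  expect_equal(unname(cf["sbp", "ptt"]) / 1000, -0.2, tolerance = 1e-6)
  expect_equal(unname(cf["dbp", "ptt"]) / 1000, -0.1, tolerance = 1e-6)
  expect_lt(abs(cf["sbp", "rri"]), 1e-6)
  expect_lt(abs(cf["sbp", "rji"]), 1e-6)
  # measured PTT = planted PTT + the documented template offset, so the
  # intercept absorbs slope * offset
  expect_equal(unname(cf["sbp", "(Intercept)"]),
               165 + 0.2 * ppg_dpeak_offset() * 1000, tolerance = 1e-6)
  # residuals vanish; predictions reproduce the targets
  pr <- predict(m, ft)
  expect_lt(max(abs(pr$sbp_hat - ft$sbp)), 1e-8)
})

test_that("constant predictors raise a rank error naming the column", {
  out <- generate_recording(frozen_synth_config(duration_s = 30, seed = 1))
  ft <- features_from_truth(out$truth)  # constant rri, ptt, rji
  expect_error(fit_mlr(ft), "rank-deficient")
  expect_error(fit_mlr(ft[1:3, ]), ">= 4")
})

test_that("Gaussian BP noise drives MLR RMSE towards its sigma", {
  sigma <- 3
  out <- generate_recording(clean_synth_config(duration_s = 240, seed = 8,
                                               bp_noise_sd = sigma))
  ft <- features_from_truth(out$truth)
  m <- fit_mlr(ft)
  rmse <- sqrt(mean(residuals(m)[, "sbp"]^2))
  expect_equal(rmse, sigma, tolerance = 0.15)
})

test_that("the full fiducial pipeline yields a negative PTT coefficient", {
  fx <- baseline_fixture()
  f <- extract_features(fx$recording)
  expect_gt(nrow(f), 40)
  m <- fit_mlr(f)
  expect_lt(coef(m)["sbp", "ptt"], 0)
  expect_lt(coef(m)["dbp", "ptt"], 0)
})
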