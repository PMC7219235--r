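# Shared fixtures. Everything is generated in code; heavyweight artifacts
# (trained models, cohorts) are computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a noise-free generator configuration with per-beat variation retained
clean_synth_config <- function(duration_s = 30, seed = 1, hr_sd = 1,
                               ptt_amplitude = 30, rji_sd = 5, ...) {
  synth_config(duration_s = duration_s, hr_sd = hr_sd,
               ptt_amplitude = ptt_amplitude, rji_sd = rji_sd,
               noise_wander_amp = 0, noise_powerline_amp = 0,
               noise_white_sd = 0, seed = seed, ...)
}

# a fully deterministic configuration (no jitter, no noise)
frozen_synth_config <- function(duration_s = 30, seed = 1, ...) {
  synth_config(duration_s = duration_s, hr_sd = 0, ptt_amplitude = 0,
               rji_sd = 0, noise_wander_amp = 0, noise_powerline_amp = 0,
               noise_white_sd = 0, seed = seed, ...)
}

# construct a bp_windows object directly (for split / outlier-rule tests)
make_windows <- function(y_sbp, y_dbp = rep(70, length(y_sbp)),
                         subject_id = rep("s1", length(y_sbp)),
                         t_end = seq_along(y_sbp), n_samples = 4L,
                         n_channels = 1L) {
  n <- length(y_sbp)
  structure(list(
    X = array(0, dim = c(n, n_samples, n_channels)),
    y_sbp = y_sbp, y_dbp = y_dbp,
    t_end = t_end, subject_id = subject_id,
    fs = 125, window_s = n_samples / 125, stride_s = 1,
    standardized = TRUE
  ), class = "bp_windows")
}

# independent scalar-loop GRU oracle, written straight from the update /
# reset / candidate equations (no shared code with the package path)
gru_oracle <- function(h_prev, x, w) {
  H <- length(h_prev)
  hx <- c(h_prev, x)
  z <- numeric(H); r <- numeric(H); hc <- numeric(H); h <- numeric(H)
  for (j in seq_len(H)) {
    az <- sum(w$Wz[, j] * hx) + w$bz[j]
    ar <- sum(w$Wr[, j] * hx) + w$br[j]
    z[j] <- 1 / (1 + exp(-az))
    r[j] <- 1 / (1 + exp(-ar))
  }
  rhx <- c(r * h_prev, x)
  for (j in seq_len(H)) {
    ah <- sum(w$Wh[, j] * rhx) + w$bh[j]
    hc[j] <- tanh(ah)
    h[j] <- (1 - z[j]) * h_prev[j] + z[j] * hc[j]
  }
  h
}

# reduced-scale cohort with subject-specific BP intercepts and a strong
# planted PTT modulation; used by the learnability / LOSO checks
learnability_cohort <- function() {
  cache_get("learn_cohort", function() {
    intercepts_s <- c(155, 165, 175)
    intercepts_d <- c(85, 95, 105)
    parts <- list()
    for (s in 1:3) {
      sc <- synth_config(duration_s = 300, ptt_amplitude = 40,
                         ptt_period_s = 20, hr_sd = 1,
                         sbp_intercept = intercepts_s[s],
                         dbp_intercept = intercepts_d[s],
                         seed = 100 + s)
      rec <- generate_recording(sc)$recording
      rec <- resample_record(filter_recording(rec), 125)
      parts[[s]] <- segment(rec, stride_s = 0.35, subject_id = paste0("s", s))
    }
    bind_windows(parts)
  })
}

learnability_train_config <- function() {
  train_config(max_epochs = 15, patience = 6, batch_size = 64, seed = 1)
}

learnability_net <- function(seed = 1) {
  bp_net(bp_net_config(in_channels = 3, scale = 1 / 8, bn_momentum = 0.9),
         seed = seed)
}

# calibration-mode training on the held-out subject's own data
calibration_run <- function() {
  cache_get("cal_run", function() {
    ds <- learnability_cohort()
    ds3 <- ds[ds$subject_id == "s3"]
    tc <- learnability_train_config()
    sp <- split_dataset(ds3, tc, mode = "calibration")
    res <- fit(learnability_net(1), sp$train, sp$val, tc)
    pred <- predict(res$net, sp$test)
    list(splits = sp, res = res, pred = pred)
  })
}

# LOSO training: s3 held out, model trained on s1 + s2
loso_run <- function() {
  cache_get("loso_run", function() {
    ds <- learnability_cohort()
    tc <- learnability_train_config()
    sp <- split_dataset(ds, tc, mode = "loso", holdout_subject = "s3")
    res <- fit(learnability_net(2), sp$train, sp$val, tc)
    pred <- predict(res$net, sp$test)
    list(splits = sp, res = res, pred = pred)
  })
}
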