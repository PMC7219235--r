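# Synthetic multi-channel cardiovascular recordings with known ground truth.
#
# The generator plants the quantities every downstream stage estimates: ECG R
# peaks, a PPG pulse delayed from each R by a slowly modulated pulse transit
# time (PTT), a BCG J wave at an R-J interval (RJI) inside the 110-250 ms
# search window, and beat SBP/DBP linearly (negatively) coupled to PTT.
# Morphology is a documented package choice (Gaussian-mixture QRS, gamma-like
# PPG pulse, Ricker/Mexican-hat J wave): only timing and coupling are
# load-bearing for the estimators.

# PPG pulse template: g(u) = (u/tau)^2 exp(-u/tau), u >= 0, normalized to
# unit peak. Peak at u = 2*tau; steepest rise at u = (2 - sqrt(2)) * tau.
PPG_TAU <- 0.12

#' Offset from PPG pulse onset to its maximum first derivative
#'
#' The synthetic PPG pulse is `(u/tau)^2 * exp(-u/tau)` with `tau = 0.12` s;
#' its steepest-rising point sits at `(2 - sqrt(2)) * tau` seconds after
#' pulse onset. Measured PTT (R to PPG-derivative peak) therefore equals the
#' planted PTT plus this constant.
#'
#' @return offset in seconds (~0.0703 s).
#' @export
ppg_dpeak_offset <- function() (2 - sqrt(2)) * PPG_TAU

#' Configuration for the synthetic recording generator
#'
#' Defaults state the emulated world: 1000 Hz acquisition, resting heart rate
#' 70 bpm with 2 bpm beat-to-beat jitter, PTT 250 ms modulated +/- 30 ms over
#' a 30 s slow (autonomic-like) cycle, J wave 180 ms after R, and BP coupled
#' negatively to PTT so that mean SBP/DBP land at 115/70 mmHg
#' (165 - 0.2 * 250 and 95 - 0.1 * 250).
#'
#' @param duration_s recording length in seconds (>= 10).
#' @param fs sampling rate in Hz.
#' @param hr_mean,hr_sd mean heart rate and beat-to-beat jitter, bpm.
#' @param ptt_mean,ptt_amplitude,ptt_period_s PTT baseline (ms), slow
#'   modulation depth (ms) and modulation period (s).
#' @param rji_mean,rji_sd R-J interval mean and per-beat jitter, ms;
#'   `rji_mean` must lie in `[110, 250]` so the J search window contains the
#'   planted peak (jittered values are truncated to `[112, 248]`).
#' @param sbp_intercept,sbp_slope,dbp_intercept,dbp_slope linear PTT -> BP
#'   coupling, mmHg and mmHg/ms; both slopes must be negative.
#' @param bp_noise_sd per-beat Gaussian BP noise, mmHg (default 0: the
#'   planted coupling is exact; noise otherwise enters through the waveforms).
#' @param noise_wander_amp,noise_powerline_amp,noise_white_sd additive
#'   baseline-wander (0.3 Hz), power-line and white-noise amplitudes,
#'   applied to every channel (arbitrary units).
#' @param powerline_hz power-line frequency in Hz.
#' @param seed integer RNG seed; generation is fully deterministic given it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 120, fs = 1000,
                         hr_mean = 70, hr_sd = 2,
                         ptt_mean = 250, ptt_amplitude = 30, ptt_period_s = 30,
                         rji_mean = 180, rji_sd = 5,
                         sbp_intercept = 165, sbp_slope = -0.2,
                         dbp_intercept = 95, dbp_slope = -0.1,
                         bp_noise_sd = 0,
                         noise_wander_amp = 0.1, noise_powerline_amp = 0.02,
                         noise_white_sd = 0.02, powerline_hz = 60,
                         seed = 1L) {
  cfg <- list(
    duration_s = duration_s, fs = fs, hr_mean = hr_mean, hr_sd = hr_sd,
    ptt_mean = ptt_mean, ptt_amplitude = ptt_amplitude,
    ptt_period_s = ptt_period_s, rji_mean = rji_mean, rji_sd = rji_sd,
    sbp_intercept = sbp_intercept, sbp_slope = sbp_slope,
    dbp_intercept = dbp_intercept, dbp_slope = dbp_slope,
    bp_noise_sd = bp_noise_sd,
    noise_wander_amp = noise_wander_amp,
    noise_powerline_amp = noise_powerline_amp,
    noise_white_sd = noise_white_sd, powerline_hz = powerline_hz,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (!(cfg$fs > 0))
    stop_cfg("synth config invalid: fs must be > 0 (got %g)", cfg$fs)
  if (!(cfg$duration_s >= 10))
    stop_cfg("synth config invalid: duration_s must be >= 10 (got %g)",
             cfg$duration_s)
  if (!(cfg$rji_mean >= 110 && cfg$rji_mean <= 250))
    stop_cfg("synth config invalid: rji_mean must lie in [110, 250] ms (got %g)",
             cfg$rji_mean)
  if (!(cfg$sbp_slope < 0))
    stop_cfg("synth config invalid: sbp_slope must be negative (got %g)",
             cfg$sbp_slope)
  if (!(cfg$dbp_slope < 0))
    stop_cfg("synth config invalid: dbp_slope must be negative (got %g)",
             cfg$dbp_slope)
  if (cfg$hr_mean <= 0 || cfg$hr_sd < 0)
    stop_cfg("synth config invalid: hr_mean must be > 0 and hr_sd >= 0")
  invisible(cfg)
}

# add a template evaluated on a restricted index range; t0 in seconds,
# shape_fn takes u = t - t0 (seconds, >= lo) and returns amplitudes
add_component <- function(x, fs, t0, lo, hi, shape_fn) {
  i1 <- max(1L, floor((t0 + lo) * fs) + 1L)
  i2 <- min(length(x), ceiling((t0 + hi) * fs) + 1L)
  if (i1 > i2) return(x)
  idx <- i1:i2
  u <- (idx - 1) / fs - t0
  x[idx] <- x[idx] + shape_fn(u)
  x
}

gauss_wave <- function(amp, mu, sd) {
  force(amp); force(mu); force(sd)
  list(amp = amp, mu = mu, sd = sd)
}

# ECG beat: Gaussian mixture forming P-QRS-T (amplitudes in arbitrary "mV")
ECG_WAVES <- list(
  gauss_wave(0.10, -0.200, 0.025),  # P
  gauss_wave(-0.12, -0.026, 0.010), # Q
  gauss_wave(1.00, 0.000, 0.011),   # R
  gauss_wave(-0.18, 0.028, 0.011),  # S
  gauss_wave(0.35, 0.220, 0.045)    # T
)

ppg_pulse_shape <- function(u) {
  v <- (u / PPG_TAU)^2 * exp(-u / PPG_TAU)
  v / (4 * exp(-2))  # unit peak (peak value at u = 2 * tau)
}

ricker_shape <- function(u, sigma = 0.02) {
  (1 - (u / sigma)^2) * exp(-u^2 / (2 * sigma^2))
}

#' Generate a synthetic synchronized ECG/PPG/BCG/BP recording
#'
#' Produces a multi-channel recording plus the ground truth used to validate
#' detectors and estimators: R times, PPG onset/derivative-peak times, J
#' times, per-beat PTT and RJI, and per-beat SBP/DBP computed as
#' `intercept + slope * PTT(ms)` (+ optional Gaussian noise). Ground truth is
#' drawn from an RNG stream independent of the waveform-noise stream, so
#' changing noise amplitudes never changes the truth.
#'
#' @param config a [synth_config()].
#' @return list with elements `recording` (class `bp_recording`: named
#'   channels `ecg`, `ppg`, `bcg`; `fs`; `bp_beats` data.frame `t`, `sbp`,
#'   `dbp`; `meta`) and `truth` (class `bp_ground_truth`).
#' @examples
#' out <- generate_recording(synth_config(duration_s = 20, seed = 7))
#' out$recording
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  t_grid <- (seq_len(n) - 1) / fs

  ## ---- beat-level truth (own RNG stream) ----
  set.seed(config$seed)
  r_times <- numeric(0)
  t_beat <- 0.5
  while (t_beat <= config$duration_s - 0.05) {
    r_times <- c(r_times, t_beat)
    hr_i <- config$hr_mean
    if (config$hr_sd > 0) {
      hr_i <- hr_i + stats::rnorm(1, 0, config$hr_sd)
      hr_i <- min(max(hr_i, 30), 220)
    }
    t_beat <- t_beat + 60 / hr_i
  }
  nb <- length(r_times)
  if (nb < 2) stop_cfg("synth config invalid: fewer than 2 beats generated")

  ptt_ms <- config$ptt_mean +
    config$ptt_amplitude * sin(2 * pi * (r_times - r_times[1]) / config$ptt_period_s)
  rji_ms <- rep(config$rji_mean, nb)
  if (config$rji_sd > 0) {
    rji_ms <- pmin(pmax(rji_ms + stats::rnorm(nb, 0, config$rji_sd), 112), 248)
  }
  sbp <- config$sbp_intercept + config$sbp_slope * ptt_ms
  dbp <- config$dbp_intercept + config$dbp_slope * ptt_ms
  if (config$bp_noise_sd > 0) {
    sbp <- sbp + stats::rnorm(nb, 0, config$bp_noise_sd)
    dbp <- dbp + stats::rnorm(nb, 0, config$bp_noise_sd)
  }

  j_times <- r_times + rji_ms / 1000
  ppg_onset <- r_times + ptt_ms / 1000
  ppg_dpeak <- ppg_onset + ppg_dpeak_offset()

  ## ---- clean waveforms ----
  ecg <- numeric(n); ppg <- numeric(n); bcg <- numeric(n)
  for (i in seq_len(nb)) {
    r <- r_times[i]
    for (w in ECG_WAVES) {
      ecg <- add_component(ecg, fs, r + w$mu, -4 * w$sd, 4 * w$sd,
                           function(u) w$amp * exp(-u^2 / (2 * w$sd^2)))
    }
    ppg <- add_component(ppg, fs, ppg_onset[i], 0, 0.9, ppg_pulse_shape)
    bcg <- add_component(bcg, fs, j_times[i], -0.08, 0.08, ricker_shape)
  }

  ## ---- additive noise (independent RNG stream) ----
  set.seed(derive_seed(config$seed, 1L))
  channels <- list(ecg = ecg, ppg = ppg, bcg = bcg)
  for (nm in names(channels)) {
    phase_w <- stats::runif(1, 0, 2 * pi)
    phase_p <- stats::runif(1, 0, 2 * pi)
    white <- stats::rnorm(n)
    channels[[nm]] <- channels[[nm]] +
      config$noise_wander_amp * sin(2 * pi * 0.3 * t_grid + phase_w) +
      config$noise_powerline_amp * sin(2 * pi * config$powerline_hz * t_grid + phase_p) +
      config$noise_white_sd * white
  }

  rec <- structure(list(
    channels = channels,
    fs = fs,
    bp_beats = data.frame(t = r_times, sbp = sbp, dbp = dbp),
    meta = list(generator = "cufflessbp::generate_recording",
                seed = config$seed, duration_s = config$duration_s)
  ), class = "bp_recording")

  truth <- structure(list(
    r_times = r_times,
    ppg_onset_times = ppg_onset,
    ppg_dpeak_times = ppg_dpeak,
    j_times = j_times,
    ptt_ms = ptt_ms,
    rji_ms = rji_ms,
    sbp_beats = sbp,
    dbp_beats = dbp
  ), class = "bp_ground_truth")

  list(recording = rec, truth = truth)
}

#' @export
print.bp_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<bp_recording> %d channels (%s), %.1f s at %g Hz, %d BP beats\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              n / x$fs, x$fs, nrow(x$bp_beats)))
  invisible(x)
}

#' @export
print.bp_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<bp_ground_truth> %d beats; PTT %.0f-%.0f ms; RJI %.0f-%.0f ms; SBP %.1f-%.1f mmHg\n",
    length(x$r_times), min(x$ptt_ms), max(x$ptt_ms),
    min(x$rji_ms), max(x$rji_ms), min(x$sbp_beats), max(x$sbp_beats)))
  invisible(x)
}

rec_duration <- function(rec) length(rec$channels[[1]]) / rec$fs
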