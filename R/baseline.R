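# Fiducial-point baseline: Pan-Tompkins R peaks, BCG J peak as the highest
# peak 110-250 ms after each R, PPG first-derivative peak; per-cycle
# RRI/PTT/RJI features with automated cycle exclusion; multiple linear
# regression to SBP/DBP. Operates at native timing resolution (features in
# seconds), independent of the 125 Hz deep-learning path.
#
# Cycle exclusion is rule-based (refractory period, J search window,
# interior-local-maximum and relative-floor checks, derivative positivity)
# rather than manual; every threshold is relative to signal statistics so
# detection is invariant to uniform amplitude scaling.

#' Detect ECG R peaks (Pan-Tompkins)
#'
#' Derivative, squaring, 150 ms moving-window integration, adaptive
#' signal/noise thresholding with a 200 ms refractory period, and refinement
#' of each detection to the local ECG maximum. All thresholds scale with the
#' signal, so detections are invariant to amplitude scaling.
#'
#' @param ecg band-passed ECG waveform.
#' @param fs sampling rate in Hz (>= 100).
#' @return strictly increasing R-peak times in seconds (empty, with a
#'   warning, if nothing is found).
#' @export
detect_r_peaks <- function(ecg, fs) {
  if (fs < 100) stop_cfg("detect_r_peaks: fs must be >= 100 Hz (got %g)", fs)
  n <- length(ecg)
  d <- c(0, diff(ecg)) * fs
  sq <- d^2
  w <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  mwi[is.na(mwi)] <- 0
  # candidate local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0]
  if (length(cand) == 0) {
    warning("no R peaks found")
    return(numeric(0))
  }
  head_n <- min(n, round(2 * fs))
  spki <- 0.5 * max(mwi[seq_len(head_n)])
  npki <- 0.5 * mean(mwi[seq_len(head_n)])
  refract <- round(0.2 * fs)
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (i - last < refract) next
    if (mwi[i] > thr) {
      spki <- 0.125 * mwi[i] + 0.875 * spki
      peaks <- c(peaks, i)
      last <- i
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  if (length(peaks) == 0) {
    warning("no R peaks found")
    return(numeric(0))
  }
  # refine to the local ECG maximum (the MWI peak lags the R wave)
  half <- round(0.10 * fs)
  r_idx <- vapply(peaks, function(i) {
    i1 <- max(1L, as.integer(i - w)); i2 <- min(n, as.integer(i + half))
    i1 + which.max(ecg[i1:i2]) - 1L
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # enforce refractory distance after refinement, keeping the larger peak
  keep <- rep(TRUE, length(r_idx))
  for (k in seq_along(r_idx)[-1]) {
    prev <- max(which(keep[seq_len(k - 1)]))
    if (r_idx[k] - r_idx[prev] < refract) {
      if (ecg[r_idx[k]] > ecg[r_idx[prev]]) keep[prev] <- FALSE else keep[k] <- FALSE
    }
  }
  (r_idx[keep] - 1) / fs
}

#' Detect BCG J peaks after each R peak
#'
#' The J peak is the highest point of the BCG between 110 and 250 ms after
#' each R peak. A cycle is invalid when the search window runs past the end
#' of the signal, the maximum sits on the window boundary (not an interior
#' local maximum, e.g. when the true J lies outside the window), or its
#' amplitude falls below a relative noise floor (25% of the median detected
#' peak amplitude).
#'
#' @param bcg band-passed BCG waveform.
#' @param fs sampling rate in Hz.
#' @param r_times R-peak times in seconds.
#' @return data.frame with `time` (J time, seconds) and `valid` flag, one
#'   row per R peak.
#' @export
detect_j_peaks <- function(bcg, fs, r_times) {
  n <- length(bcg)
  res <- data.frame(time = rep(NA_real_, length(r_times)),
                    valid = rep(FALSE, length(r_times)))
  peak_val <- rep(NA_real_, length(r_times))
  for (k in seq_along(r_times)) {
    i1 <- round((r_times[k] + 0.110) * fs) + 1L
    i2 <- round((r_times[k] + 0.250) * fs) + 1L
    if (i1 < 1L || i2 > n) next
    seg <- bcg[i1:i2]
    j <- which.max(seg)
    interior <- j > 1L && j < length(seg)
    if (!interior) next
    res$time[k] <- (i1 + j - 2L) / fs
    peak_val[k] <- seg[j]
    res$valid[k] <- TRUE
  }
  # relative noise floor over provisionally valid cycles
  if (any(res$valid)) {
    floor_v <- 0.25 * stats::median(peak_val[res$valid])
    res$valid <- res$valid & !is.na(peak_val) & peak_val >= floor_v
  }
  res
}

#' Detect the PPG first-derivative peak in each cardiac cycle
#'
#' Differentiates the PPG and takes, per cycle, the maximum of the
#' derivative within `(r, r + 0.6]` s (a window covering physiologic PTT
#' while preventing next-beat capture at heart rates of 50 bpm and above).
#' A cycle is invalid if the window is truncated or contains no positive
#' derivative maximum.
#'
#' @param ppg band-passed PPG waveform.
#' @param fs sampling rate in Hz.
#' @param r_times R-peak times in seconds.
#' @return data.frame with `time` (derivative-peak time, seconds) and
#'   `valid`, one row per R peak.
#' @export
detect_dppg_peaks <- function(ppg, fs, r_times) {
  n <- length(ppg)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (ppg[3:n] - ppg[1:(n - 2)]) * fs / 2
  # centered ~11 ms moving average: suppresses in-band noise jitter of the
  # derivative argmax without biasing its location (symmetric kernel)
  k <- max(1L, round(0.011 * fs))
  if (k %% 2 == 0) k <- k + 1L
  if (k > 1) {
    ds <- stats::filter(d, rep(1 / k, k), sides = 2)
    d <- ifelse(is.na(ds), d, as.numeric(ds))
  }
  res <- data.frame(time = rep(NA_real_, length(r_times)),
                    valid = rep(FALSE, length(r_times)))
  for (k in seq_along(r_times)) {
    i1 <- round(r_times[k] * fs) + 2L
    i2 <- round((r_times[k] + 0.600) * fs) + 1L
    if (i1 < 2L || i2 > n - 1L) next
    seg <- d[i1:i2]
    j <- which.max(seg)
    if (seg[j] <= 0) next
    res$time[k] <- (i1 + j - 2L) / fs
    res$valid[k] <- TRUE
  }
  res
}

#' Per-cycle interval features
#'
#' Combines the three detectors into one feature row per cardiac cycle:
#' RRI (R to next R), PTT (R to PPG-derivative peak) and RJI (R to J peak),
#' all in seconds. Cycles with any missing fiducial (or no following R peak)
#' are excluded; the exclusion fraction is attached as an attribute.
#'
#' @param r_times R-peak times (seconds).
#' @param j data.frame from [detect_j_peaks()].
#' @param dppg data.frame from [detect_dppg_peaks()].
#' @return data.frame `r_time`, `rri`, `ptt`, `rji` (class `bp_features`),
#'   with attribute `excluded_frac`.
#' @export
build_features <- function(r_times, j, dppg) {
  nb <- length(r_times)
  if (nb < 2) stop_cfg("build_features: need at least 2 R peaks")
  stopifnot(nrow(j) == nb, nrow(dppg) == nb)
  n_cycles <- nb - 1L  # a cycle spans consecutive R peaks
  cyc <- seq_len(n_cycles)
  rri <- diff(r_times)
  valid <- j$valid[cyc] & dppg$valid[cyc]
  if (!any(valid)) stop_cfg("build_features: zero valid cardiac cycles")
  out <- data.frame(
    r_time = r_times[cyc][valid],
    rri = rri[valid],
    ptt = dppg$time[cyc][valid] - r_times[cyc][valid],
    rji = j$time[cyc][valid] - r_times[cyc][valid]
  )
  class(out) <- c("bp_features", "data.frame")
  attr(out, "excluded_frac") <- 1 - sum(valid) / n_cycles
  out
}

#' Build interval features from generator ground truth
#'
#' Convenience constructor of exact per-cycle features from a
#' `bp_ground_truth`, used for noiseless regression checks and as the
#' oracle against which the detectors are validated.
#'
#' @param truth a `bp_ground_truth`.
#' @return `bp_features` data.frame with `sbp`/`dbp` columns attached.
#' @export
features_from_truth <- function(truth) {
  nb <- length(truth$r_times)
  keep <- seq_len(nb - 1)
  out <- data.frame(
    r_time = truth$r_times[keep],
    rri = diff(truth$r_times),
    ptt = truth$ppg_dpeak_times[keep] - truth$r_times[keep],
    rji = truth$j_times[keep] - truth$r_times[keep],
    sbp = truth$sbp_beats[keep],
    dbp = truth$dbp_beats[keep]
  )
  class(out) <- c("bp_features", "data.frame")
  attr(out, "excluded_frac") <- 0
  out
}

#' Attach reference BP beats to feature rows
#'
#' Matches each cycle to the nearest annotated beat within 40% of the
#' median RRI (the reference beat of the same cardiac cycle); unmatched
#' rows are dropped.
#'
#' @param features a `bp_features` data.frame.
#' @param bp_beats data.frame `t`, `sbp`, `dbp`.
#' @return the features with `sbp` and `dbp` columns.
#' @export
attach_bp <- function(features, bp_beats) {
  tol <- 0.4 * stats::median(features$rri)
  idx <- vapply(features$r_time, function(r) {
    k <- which.min(abs(bp_beats$t - r))
    if (abs(bp_beats$t[k] - r) <= tol) k else NA_integer_
  }, integer(1))
  keep <- !is.na(idx)
  out <- features[keep, , drop = FALSE]
  out$sbp <- bp_beats$sbp[idx[keep]]
  out$dbp <- bp_beats$dbp[idx[keep]]
  out
}

#' Run the whole fiducial pipeline on a recording
#'
#' Band-passes the channels (unless already filtered), runs the three
#' detectors, builds per-cycle features and attaches the reference beats.
#'
#' @param rec a `bp_recording` at native rate.
#' @return `bp_features` with `sbp`/`dbp` columns.
#' @export
extract_features <- function(rec) {
  stopifnot(inherits(rec, "bp_recording"))
  if (!isTRUE(rec$meta$filtered)) rec <- filter_recording(rec)
  r_times <- detect_r_peaks(rec$channels$ecg, rec$fs)
  if (length(r_times) < 2) stop_cfg("extract_features: too few R peaks")
  j <- detect_j_peaks(rec$channels$bcg, rec$fs, r_times)
  dppg <- detect_dppg_peaks(rec$channels$ppg, rec$fs, r_times)
  feats <- build_features(r_times, j, dppg)
  attach_bp(feats, rec$bp_beats)
}

#' Fit the multiple linear regression baseline
#'
#' Ordinary least squares of SBP and DBP on the per-cycle features RRI, PTT
#' and RJI (seconds).
#'
#' @param features a `bp_features` data.frame.
#' @param sbp,dbp reference BP per row, mmHg; taken from the feature columns
#'   when omitted.
#' @return object of class `bp_mlr` with `lm` fits for both targets.
#' @export
fit_mlr <- function(features, sbp = features$sbp, dbp = features$dbp) {
  if (nrow(features) < 4)
    stop_cfg("fit_mlr: need >= 4 valid cycles (3 predictors + intercept)")
  X <- as.data.frame(features[, c("rri", "ptt", "rji")])
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < 4) {
    sds <- vapply(X, stats::sd, numeric(1))
    bad <- names(sds)[sds == 0 | !is.finite(sds)]
    if (length(bad) == 0) bad <- "collinear predictors"
    stop_cfg("fit_mlr: rank-deficient design (%s)", paste(bad, collapse = ", "))
  }
  df <- cbind(X, .sbp = sbp, .dbp = dbp)
  obj <- structure(list(
    sbp_fit = stats::lm(.sbp ~ rri + ptt + rji, data = df),
    dbp_fit = stats::lm(.dbp ~ rri + ptt + rji, data = df),
    n = nrow(df)
  ), class = "bp_mlr")
  obj
}

#' @export
coef.bp_mlr <- function(object, ...) {
  rbind(sbp = stats::coef(object$sbp_fit), dbp = stats::coef(object$dbp_fit))
}

#' Predict BP from interval features
#'
#' @param object a `bp_mlr`.
#' @param newdata `bp_features` data.frame with `rri`, `ptt`, `rji`.
#' @param ... unused.
#' @return list with `sbp_hat` and `dbp_hat`, mmHg.
#' @export
predict.bp_mlr <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  list(sbp_hat = unname(stats::predict(object$sbp_fit, nd)),
       dbp_hat = unname(stats::predict(object$dbp_fit, nd)))
}

#' @export
print.bp_mlr <- function(x, ...) {
  cat(sprintf("<bp_mlr> OLS of SBP/DBP on (rri, ptt, rji), n = %d cycles\n", x$n))
  cf <- coef(x)
  print(round(cf, 4))
  invisible(x)
}

#' @export
residuals.bp_mlr <- function(object, ...) {
  cbind(sbp = stats::residuals(object$sbp_fit),
        dbp = stats::residuals(object$dbp_fit))
}
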