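# Preprocessing: per-channel band-pass at the native rate, whole-record
# resampling to 125 Hz, 5-s sliding-window segmentation with end-of-window
# BP targets, and mean +/- 1.96 SD target-outlier elimination.
#
# Pipeline order (documented choice): filter at native rate -> resample the
# full record -> segment. Beat annotations are times in seconds and are
# untouched by resampling.

#' Band-pass filter every channel of a recording
#'
#' Applies the per-channel zero-phase Butterworth band-pass (see
#' [default_filter_specs()]) at the recording's native rate.
#'
#' @param rec a `bp_recording`.
#' @param specs data.frame of filter specs (default [default_filter_specs()]).
#' @return the filtered `bp_recording`.
#' @export
filter_recording <- function(rec, specs = default_filter_specs()) {
  stopifnot(inherits(rec, "bp_recording"))
  for (i in seq_len(nrow(specs))) {
    ch <- specs$channel[i]
    if (!ch %in% names(rec$channels)) next
    rec$channels[[ch]] <- bandpass(rec$channels[[ch]], rec$fs, specs[i, ])
  }
  rec$meta$filtered <- TRUE
  rec
}

#' Resample a recording to a lower rate
#'
#' FFT-based resampling of every channel to `fs_target` (default 125 Hz, the
#' rate used for learning). Upsampling is out of scope and raises an error.
#' Beat annotations are expressed in seconds and are unchanged.
#'
#' @param rec a `bp_recording`.
#' @param fs_target target sampling rate in Hz (`<= rec$fs`).
#' @return the resampled `bp_recording`.
#' @export
resample_record <- function(rec, fs_target = 125) {
  stopifnot(inherits(rec, "bp_recording"))
  if (fs_target > rec$fs)
    stop_cfg("upsampling requested (%g -> %g Hz): out of scope",
             rec$fs, fs_target)
  if (fs_target == rec$fs) return(rec)
  n <- length(rec$channels[[1]])
  n_out <- round(n * fs_target / rec$fs)
  rec$channels <- lapply(rec$channels, resample_fft, n_out = n_out)
  rec$fs <- fs_target
  rec
}

#' Segment a recording into fixed-length windows with BP targets
#'
#' Cuts half-open `[t, t + window_s)` windows advanced by `stride_s`.
#' The default stride corresponds to a 1 ms shift at the native 1000 Hz,
#' which after the 125 Hz resample becomes the minimum realizable shift of
#' one sample = 8 ms. The target (SBP, DBP) of a window is the beat value in
#' force at the window's final sample (sample-and-hold interpolation of the
#' beat series); windows ending before the first annotated beat are dropped.
#'
#' @param rec a `bp_recording` (typically filtered and resampled).
#' @param window_s window length in seconds (default 5).
#' @param stride_s window shift in seconds (default 0.008).
#' @param channels channel subset used as model input, in order.
#' @param standardize per-window, per-channel zero-mean/unit-variance
#'   scaling (default TRUE); raw sensor units are arbitrary across channels.
#' @param subject_id subject label attached to every window.
#' @return object of class `bp_windows`: array `X` (windows x samples x
#'   channels), numeric `y_sbp`, `y_dbp`, `t_end` (time of final sample),
#'   `subject_id`, plus `fs`, `window_s`, `stride_s`.
#' @export
segment <- function(rec, window_s = 5, stride_s = 0.008,
                    channels = c("ecg", "ppg", "bcg"),
                    standardize = TRUE, subject_id = "s1") {
  stopifnot(inherits(rec, "bp_recording"))
  missing <- setdiff(channels, names(rec$channels))
  if (length(missing) > 0)
    stop_cfg("unknown channel(s): %s", paste(missing, collapse = ", "))
  fs <- rec$fs
  n <- length(rec$channels[[1]])
  w <- round(window_s * fs)
  if (n < w)
    stop_cfg("recording too short to segment: %.3f s < window %.3f s",
             n / fs, window_s)
  starts <- integer(0)
  k <- 0L
  repeat {
    i0 <- round(k * stride_s * fs) + 1L
    if (i0 + w - 1L > n) break
    starts <- c(starts, i0)
    k <- k + 1L
  }
  t_final <- (starts - 1 + w - 1) / fs
  tb <- rec$bp_beats$t
  if (length(tb) == 0)
    stop_cfg("recording has no beat BP annotations; cannot assign targets")
  idx <- findInterval(t_final + 1e-9, tb)
  keep <- idx >= 1L
  starts <- starts[keep]; t_final <- t_final[keep]; idx <- idx[keep]
  if (length(starts) == 0)
    stop_cfg("no window ends after the first beat annotation")
  nw <- length(starts)
  X <- array(0, dim = c(nw, w, length(channels)),
             dimnames = list(NULL, NULL, channels))
  for (ci in seq_along(channels)) {
    sig <- rec$channels[[channels[ci]]]
    for (wi in seq_len(nw)) {
      seg <- sig[starts[wi]:(starts[wi] + w - 1L)]
      if (standardize) {
        s <- stats::sd(seg)
        seg <- (seg - mean(seg)) / (if (is.finite(s) && s > 0) s else 1)
      }
      X[wi, , ci] <- seg
    }
  }
  structure(list(
    X = X,
    y_sbp = rec$bp_beats$sbp[idx],
    y_dbp = rec$bp_beats$dbp[idx],
    t_end = t_final,
    subject_id = rep(subject_id, nw),
    fs = fs, window_s = window_s, stride_s = stride_s,
    standardized = standardize
  ), class = "bp_windows")
}

#' @export
print.bp_windows <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf(
    "<bp_windows> %d windows of %d samples x %d channel(s) (%s) at %g Hz; %d subject(s)\n",
    d[1], d[2], d[3], paste(dimnames(x$X)[[3]], collapse = ", "), x$fs,
    length(unique(x$subject_id))))
  cat(sprintf("  SBP %.1f-%.1f mmHg, DBP %.1f-%.1f mmHg\n",
              min(x$y_sbp), max(x$y_sbp), min(x$y_dbp), max(x$y_dbp)))
  invisible(x)
}

#' @export
length.bp_windows <- function(x) dim(x$X)[1]

#' Subset a windowed dataset
#'
#' @param x a `bp_windows`.
#' @param i window indices (any standard subscript).
#' @param ... unused.
#' @return a `bp_windows` containing the selected windows.
#' @export
`[.bp_windows` <- function(x, i, ...) {
  out <- x
  out$X <- x$X[i, , , drop = FALSE]
  out$y_sbp <- x$y_sbp[i]
  out$y_dbp <- x$y_dbp[i]
  out$t_end <- x$t_end[i]
  out$subject_id <- x$subject_id[i]
  out
}

#' Concatenate windowed datasets
#'
#' @param ... `bp_windows` objects with identical window shape.
#' @return the combined `bp_windows`.
#' @export
bind_windows <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "bp_windows")) parts <- parts[[1]]
  stopifnot(all(vapply(parts, inherits, logical(1), "bp_windows")))
  dims <- vapply(parts, function(p) dim(p$X)[2:3], numeric(2))
  if (!all(dims == dims[, 1]))
    stop_cfg("cannot bind windows of different shapes")
  out <- parts[[1]]
  nw <- sum(vapply(parts, function(p) dim(p$X)[1], numeric(1)))
  X <- array(0, dim = c(nw, dim(out$X)[2], dim(out$X)[3]),
             dimnames = dimnames(out$X))
  at <- 1L
  for (p in parts) {
    k <- dim(p$X)[1]
    if (k > 0) X[at:(at + k - 1L), , ] <- p$X
    at <- at + k
  }
  out$X <- X
  out$y_sbp <- unlist(lapply(parts, `[[`, "y_sbp"))
  out$y_dbp <- unlist(lapply(parts, `[[`, "y_dbp"))
  out$t_end <- unlist(lapply(parts, `[[`, "t_end"))
  out$subject_id <- unlist(lapply(parts, `[[`, "subject_id"))
  out
}

#' Retention band of the target-outlier rule
#'
#' @param mean_v,sd_v mean and SD of a BP target series, mmHg.
#' @return numeric `c(low, high)`: `mean -/+ 1.96 * SD`.
#' @export
bp_target_band <- function(mean_v, sd_v) {
  c(mean_v - 1.96 * sd_v, mean_v + 1.96 * sd_v)
}

#' Remove target outliers from a windowed dataset
#'
#' Drops every window whose SBP or DBP target falls outside
#' `mean +/- 1.96 * SD` of that target over the dataset passed in (a window
#' is dropped if either target is outside its band). With SD = 0 the band
#' degenerates to the single value and nothing is removed. The rule is
#' applied exactly once; it is not exactly idempotent because the retained
#' subset has its own mean/SD.
#'
#' @param ds a `bp_windows`.
#' @return the filtered `bp_windows`, with attribute `n_removed`.
#' @export
remove_outlier_targets <- function(ds) {
  stopifnot(inherits(ds, "bp_windows"))
  if (length(ds) == 0) stop_cfg("empty dataset")
  keep <- rep(TRUE, length(ds))
  for (tgt in c("y_sbp", "y_dbp")) {
    y <- ds[[tgt]]
    s <- stats::sd(y)
    if (!is.finite(s) || s == 0) next
    band <- bp_target_band(mean(y), s)
    keep <- keep & y >= band[1] & y <= band[2]
  }
  out <- ds[which(keep)]
  attr(out, "n_removed") <- sum(!keep)
  out
}
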