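# Digital filtering primitives.
#
# The environment ships no signal-processing package, so the 2nd-order
# Butterworth band-pass (analog prototype -> lowpass-to-bandpass transform ->
# bilinear transform) and zero-phase forward-backward filtering are
# implemented here and validated against frequency-response oracles in the
# test suite. "Second order" follows the biosignal convention: an order-2
# prototype, i.e. a 4th-order band-pass transfer function with -3 dB points
# at the two cutoffs.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

polyval_desc <- function(coef, z) {
  # coefficients in descending powers
  acc <- 0 + 0i
  for (c0 in coef) acc <- acc * z + c0
  acc
}

#' Design a Butterworth band-pass filter
#'
#' Designs a digital Butterworth band-pass by bilinear transform of a
#' prewarped analog prototype. `order` is the prototype order (the
#' conventional "order" quoted for band-pass biosignal filters); the
#' resulting transfer function has `2 * order` poles.
#'
#' @param low_hz,high_hz band edges in Hz (-3 dB points), `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @param order prototype order (default 2).
#' @return list with numerator `b` and denominator `a` coefficients
#'   (descending powers of z, `a[1] = 1`).
#' @examples
#' ba <- butter_bandpass(0.5, 35, fs = 1000)
#' @export
butter_bandpass <- function(low_hz, high_hz, fs, order = 2) {
  if (!(low_hz > 0 && high_hz > low_hz))
    stop_cfg("invalid band: need 0 < low_hz (%g) < high_hz (%g)", low_hz, high_hz)
  if (high_hz >= fs / 2)
    stop_cfg("cutoff %g Hz at or above Nyquist (%g Hz)", high_hz, fs / 2)
  # prewarped analog edges
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # analog Butterworth prototype poles on the unit circle, left half plane
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # lowpass -> bandpass: each prototype pole maps to a conjugate-free pair
  pb <- complex(0)
  for (p in p_lp) {
    disc <- sqrt((p * bw / 2)^2 - w0^2)
    pb <- c(pb, p * bw / 2 + disc, p * bw / 2 - disc)
  }
  # bilinear transform; band-pass zeros: order at z = 1 (s = 0), order at
  # z = -1 (s = infinity)
  zp <- (2 * fs + pb) / (2 * fs - pb)
  zz <- c(rep(1 + 0i, order), rep(-1 + 0i, order))
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(zz))
  # unit gain at the digital image of the analog centre frequency
  z0 <- exp(1i * 2 * atan(w0 / (2 * fs)))
  g <- Mod(polyval_desc(a, z0) / polyval_desc(b, z0))
  list(b = b * g, a = a)
}

#' Frequency response of a digital filter
#'
#' Evaluates `H(e^{i 2 pi f / fs})` for coefficient vectors in descending
#' powers of z. Used as the numerical oracle for filter-design tests.
#'
#' @param ba list with `b` and `a` as returned by [butter_bandpass()].
#' @param f_hz frequencies at which to evaluate, in Hz.
#' @param fs sampling rate in Hz.
#' @return complex response, same length as `f_hz`.
#' @export
freqz_ba <- function(ba, f_hz, fs) {
  z <- exp(1i * 2 * pi * f_hz / fs)
  vapply(z, function(zz) {
    polyval_desc(ba$b + 0i, zz) / polyval_desc(ba$a + 0i, zz)
  }, complex(1))
}

# Single-pass IIR filter (difference equation), vectorized through
# stats::filter: FIR part by one-sided convolution, AR part recursively.
iir_filter <- function(ba, x) {
  b <- ba$b / ba$a[1]
  a <- ba$a / ba$a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xp)]
  if (length(a) > 1) {
    as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  } else {
    v
  }
}

# Edge extension length: long enough for the slowest pole to decay to ~1e-6,
# so the zero-initial-condition transient never reaches the kept samples.
filt_edge_len <- function(ba, n) {
  r <- suppressWarnings(max(Mod(polyroot(rev(ba$a)))))
  if (!is.finite(r) || r >= 1) r <- 0.999
  need <- ceiling(log(1e-6) / log(max(r, 0.5)))
  max(3 * (length(ba$a) - 1), min(n - 1, need))
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forwards and backwards with odd (reflected) edge
#' extension, giving zero phase distortion so fiducial timings (R, J, PPG
#' derivative peaks) are not skewed by group delay. Output length equals
#' input length. The effective magnitude response is `|H|^2`.
#'
#' @param ba filter coefficients from [butter_bandpass()].
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @export
filtfilt_ba <- function(ba, x) {
  n <- length(x)
  min_len <- 3 * (length(ba$a) - 1)
  if (n <= min_len)
    stop_cfg("signal too short to filter: %d samples (need > %d)", n, min_len)
  edge <- filt_edge_len(ba, n)
  pre <- 2 * x[1] - x[(edge + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - edge)]
  y <- iir_filter(ba, c(pre, x, post))
  y <- rev(iir_filter(ba, rev(y)))
  y[(edge + 1):(edge + n)]
}

#' Band-pass filter specifications for each channel
#'
#' The per-channel 2nd-order Butterworth band edges used to remove baseline
#' wander and power-line noise before windowing: ECG 0.5-35 Hz, BCG 4-15 Hz,
#' PPG 0.5-15 Hz.
#'
#' @return data.frame with columns `channel`, `hpf_hz`, `lpf_hz`, `order`.
#' @export
default_filter_specs <- function() {
  data.frame(
    channel = c("ecg", "bcg", "ppg"),
    hpf_hz = c(0.5, 4, 0.5),
    lpf_hz = c(35, 15, 15),
    order = 2L,
    stringsAsFactors = FALSE
  )
}

#' Band-pass filter one channel
#'
#' Zero-phase 2nd-order Butterworth band-pass of a single waveform.
#'
#' @param x numeric waveform.
#' @param fs sampling rate in Hz.
#' @param spec one-row data.frame (or list) with `hpf_hz`, `lpf_hz`, `order`.
#' @return filtered waveform of equal length.
#' @export
bandpass <- function(x, fs, spec) {
  spec <- as.list(spec)
  if (!(spec$hpf_hz > 0 && spec$hpf_hz < spec$lpf_hz))
    stop_cfg("filter spec invalid: need 0 < hpf (%g) < lpf (%g)",
             spec$hpf_hz, spec$lpf_hz)
  if (spec$lpf_hz >= fs / 2)
    stop_cfg("cutoff %g Hz at or above Nyquist (%g Hz)", spec$lpf_hz, fs / 2)
  ba <- butter_bandpass(spec$hpf_hz, spec$lpf_hz, fs, order = spec$order %||% 2L)
  filtfilt_ba(ba, x)
}

#' FFT-based resampling of a waveform
#'
#' Resamples by truncating the discrete spectrum (downsampling only), the
#' standard Fourier method. Appropriate here because every channel is
#' band-limited by the preceding band-pass stage.
#'
#' @param x numeric signal.
#' @param n_out target length.
#' @return resampled signal of length `n_out`.
#' @export
resample_fft <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  if (n_out > n) stop_cfg("upsampling (%d -> %d) is out of scope", n, n_out)
  X <- stats::fft(x)
  Z <- complex(n_out)
  m <- n_out %/% 2
  if (n_out %% 2 == 1) {
    Z[seq_len(m + 1)] <- X[seq_len(m + 1)]              # DC .. +m
    if (m >= 1) Z[n_out - seq_len(m) + 1] <- X[n - seq_len(m) + 1]  # -1 .. -m
  } else {
    if (m >= 1) {
      Z[seq_len(m)] <- X[seq_len(m)]                    # DC .. +(m-1)
      if (m >= 2)
        Z[n_out - seq_len(m - 1) + 1] <- X[n - seq_len(m - 1) + 1]  # -1 .. -(m-1)
      # shared Nyquist bin: fold the conjugate pair so the result stays real
      Z[m + 1] <- Re(X[m + 1] + X[n - m + 1])
    }
  }
  Re(stats::fft(Z, inverse = TRUE)) / n
}
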