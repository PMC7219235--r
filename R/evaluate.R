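# Evaluation suite: regression metrics, Bland-Altman limits of agreement,
# AAMI pass/fail, BHS grading, attention heat-map section arithmetic, and a
# JSON-serializable report.
#
# Conventions (documented): differences/errors are estimate - reference;
# sample (n-1) standard deviations throughout; the "SD" quoted next to MAE
# is the SD of absolute errors, while the AAMI SD is the SD of signed
# errors; all threshold comparisons are inclusive.

#' Regression accuracy metrics
#'
#' @param y_true,y_hat reference and estimated values (equal length).
#' @return list with `rmse`, `mae`, `sd_abs_err` (sample SD of absolute
#'   errors) and `r2` (`1 - SSres/SStot`).
#' @export
regression_metrics <- function(y_true, y_hat) {
  stopifnot(length(y_true) == length(y_hat), length(y_true) > 0)
  e <- y_hat - y_true
  sstot <- sum((y_true - mean(y_true))^2)
  if (sstot == 0)
    stop_cfg("regression_metrics: zero-variance reference; R2 undefined")
  list(
    rmse = sqrt(mean(e^2)),
    mae = mean(abs(e)),
    sd_abs_err = if (length(e) > 1) stats::sd(abs(e)) else 0,
    r2 = 1 - sum(e^2) / sstot
  )
}

#' Bland-Altman limits of agreement
#'
#' Differences are `y_hat - y_true`; limits of agreement are
#' `mean(diff) +/- 1.96 * SD(diff)` (sample SD).
#'
#' @param y_true,y_hat reference and estimated values.
#' @return list with `mean_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(y_true, y_hat) {
  stopifnot(length(y_true) == length(y_hat), length(y_true) >= 2)
  d <- y_hat - y_true
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' AAMI criterion check
#'
#' Passes when the mean signed error is within +/- 5 mmHg and the SD of
#' signed errors is at most 8 mmHg (inclusive). The standard's
#' subject-count requirement (>= 85) is reported as a warning flag, not a
#' failure.
#'
#' @param y_true,y_hat reference and estimated values.
#' @param n_subjects number of subjects behind the errors (optional).
#' @return list with `mean_error`, `sd_error`, `pass`,
#'   `n_subjects_sufficient`.
#' @export
aami_check <- function(y_true, y_hat, n_subjects = NA_integer_) {
  stopifnot(length(y_true) == length(y_hat), length(y_true) >= 2)
  e <- y_hat - y_true
  me <- mean(e)
  se <- stats::sd(e)
  list(mean_error = me, sd_error = se,
       pass = abs(me) <= 5 && se <= 8,
       n_subjects_sufficient = if (is.na(n_subjects)) NA else n_subjects >= 85)
}

BHS_TABLE <- data.frame(
  grade = c("A", "B", "C"),
  p5 = c(60, 50, 40),
  p10 = c(85, 75, 65),
  p15 = c(95, 90, 80)
)

#' BHS cumulative-error grading
#'
#' Computes the percentages of absolute errors within 5, 10 and 15 mmHg and
#' assigns the best grade whose three thresholds are all met (A: 60/85/95,
#' B: 50/75/90, C: 40/65/80, inclusive), otherwise D.
#'
#' @param y_true,y_hat reference and estimated values.
#' @return list with `p5`, `p10`, `p15` (percent) and `grade`.
#' @export
bhs_grade <- function(y_true, y_hat) {
  stopifnot(length(y_true) == length(y_hat), length(y_true) >= 1)
  ae <- abs(y_hat - y_true)
  p <- vapply(c(5, 10, 15), function(k) 100 * mean(ae <= k), numeric(1))
  grade <- "D"
  for (i in seq_len(nrow(BHS_TABLE))) {
    row <- BHS_TABLE[i, ]
    if (p[1] >= row$p5 && p[2] >= row$p10 && p[3] >= row$p15) {
      grade <- row$grade
      break
    }
  }
  list(p5 = p[1], p10 = p[2], p15 = p[3], grade = grade)
}

#' Attention heat-map section arithmetic
#'
#' The CNN reduces a 625-sample (5 s at 125 Hz) window to 8 time steps, so
#' each attention weight covers one section of `3^4 = 81` samples (648 ms);
#' the final section is truncated to 58 samples (464 ms). For each section
#' the mean attention weight over all windows and the interval from the end
#' of the section to the window end (the target BP time) are reported.
#'
#' @param attention matrix of attention weights, one row per window.
#' @param window_len window length in samples (default 625).
#' @param fs sampling rate in Hz (default 125).
#' @param section_len samples per section (default 81, the cumulative
#'   pooling stride).
#' @return data.frame `section`, `start_sample`, `end_sample` (0-based,
#'   half-open), `duration_ms`, `time_to_end_s`, `mean_weight`.
#' @export
attention_sections <- function(attention, window_len = 625, fs = 125,
                               section_len = 81) {
  if (is.null(dim(attention))) attention <- matrix(attention, nrow = 1)
  n_sec <- ncol(attention)
  if (ceiling(window_len / section_len) != n_sec)
    stop_cfg("attention length %d inconsistent with %d-sample window (%d sections expected)",
             n_sec, window_len, ceiling(window_len / section_len))
  start <- (seq_len(n_sec) - 1) * section_len
  end <- pmin(seq_len(n_sec) * section_len, window_len)
  data.frame(
    section = seq_len(n_sec),
    start_sample = start,
    end_sample = end,
    duration_ms = (end - start) / fs * 1000,
    time_to_end_s = (window_len - end) / fs,
    mean_weight = colMeans(attention)
  )
}

#' Full evaluation report for one estimator
#'
#' Bundles regression metrics, Bland-Altman, AAMI and BHS for SBP and DBP.
#'
#' @param sbp_true,sbp_hat,dbp_true,dbp_hat reference and estimated series.
#' @param n_subjects subjects represented (for the AAMI sufficiency flag).
#' @param label free-form estimator label carried in the report.
#' @return object of class `bp_eval_report`.
#' @export
eval_report <- function(sbp_true, sbp_hat, dbp_true, dbp_hat,
                        n_subjects = NA_integer_, label = "estimator") {
  one <- function(yt, yh) {
    c(regression_metrics(yt, yh),
      list(bland_altman = bland_altman(yt, yh),
           aami = aami_check(yt, yh, n_subjects),
           bhs = bhs_grade(yt, yh)))
  }
  structure(list(label = label, n = length(sbp_true),
                 n_subjects = n_subjects,
                 sbp = one(sbp_true, sbp_hat),
                 dbp = one(dbp_true, dbp_hat)),
            class = "bp_eval_report")
}

#' @export
print.bp_eval_report <- function(x, ...) {
  cat(sprintf("<bp_eval_report> %s (n = %d)\n", x$label, x$n))
  for (tgt in c("sbp", "dbp")) {
    m <- x[[tgt]]
    cat(sprintf(
      "  %s: RMSE %.2f  MAE %.2f +/- %.2f  R2 %.2f | BA %.2f [%.2f, %.2f] | AAMI %s (ME %.2f, SD %.2f) | BHS %s (%.0f/%.0f/%.0f%%)\n",
      toupper(tgt), m$rmse, m$mae, m$sd_abs_err, m$r2,
      m$bland_altman$mean_diff, m$bland_altman$loa_low, m$bland_altman$loa_high,
      if (m$aami$pass) "pass" else "FAIL", m$aami$mean_error, m$aami$sd_error,
      m$bhs$grade, m$bhs$p5, m$bhs$p10, m$bhs$p15))
  }
  invisible(x)
}

#' Write / read an evaluation report as JSON
#'
#' @param report a `bp_eval_report`.
#' @param path JSON file path.
#' @return `path` (write) or the `bp_eval_report` (read).
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "bp_eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "bp_eval_report")
}

#' Bland-Altman plot of a report
#'
#' @param x a `bp_eval_report`.
#' @param y_true,y_hat the series to plot (the report stores only
#'   summaries).
#' @param ... passed to [graphics::plot()].
#' @export
plot.bp_eval_report <- function(x, y_true, y_hat, ...) {
  d <- y_hat - y_true
  m <- mean(d); s <- stats::sd(d)
  graphics::plot((y_hat + y_true) / 2, d,
                 xlab = "mean of estimate and reference (mmHg)",
                 ylab = "difference (mmHg)", ...)
  graphics::abline(h = m, col = "blue")
  graphics::abline(h = m + c(-1.96, 1.96) * s, col = "orange", lty = 2)
  invisible(x)
}
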