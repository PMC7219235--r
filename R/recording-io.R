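# Reading and writing recordings.
#
# CSV layout: header `time,ecg,ppg,bcg`, one row per sample. Beat-level BP
# annotations and the sampling rate travel in a JSON sidecar
# `<name>.beats.json` so that annotation times (seconds) survive any
# waveform-precision round trip exactly.

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".beats.json")
}

REQUIRED_CHANNELS <- c("ecg", "ppg", "bcg")

#' Write a recording to disk
#'
#' @param rec a `bp_recording`.
#' @param path output file path.
#' @param format only `"csv"` is supported. EDF is not available in this
#'   build (no EDF library in the environment) and raises an error.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "bp_recording"))
  if (format == "edf")
    stop_cfg("format 'edf' is not supported in this build; use 'csv'")
  n <- length(rec$channels[[1]])
  df <- data.frame(time = (seq_len(n) - 1) / rec$fs)
  for (nm in names(rec$channels)) df[[nm]] <- rec$channels[[nm]]
  data.table::fwrite(df, path)
  side <- list(
    fs = rec$fs,
    beats = lapply(seq_len(nrow(rec$bp_beats)), function(i) {
      list(t = rec$bp_beats$t[i], sbp = rec$bp_beats$sbp[i],
           dbp = rec$bp_beats$dbp[i])
    }),
    meta = rec$meta
  )
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from disk
#'
#' Reads a CSV waveform file written by [write_recording()] together with
#' its `.beats.json` sidecar. All of `ecg`, `ppg`, `bcg` must be present.
#'
#' @param path CSV file path.
#' @return a `bp_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_cfg("recording file not found: %s", path)
  df <- data.table::fread(path, data.table = FALSE)
  if (!"time" %in% names(df))
    stop_cfg("malformed recording %s: missing 'time' column", path)
  missing <- setdiff(REQUIRED_CHANNELS, names(df))
  if (length(missing) > 0)
    stop_cfg("malformed recording %s: missing channel column(s): %s",
             path, paste(missing, collapse = ", "))
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    fs <- side$fs
    beats <- as.data.frame(side$beats)
    if (nrow(beats) == 0) beats <- data.frame(t = numeric(0), sbp = numeric(0),
                                              dbp = numeric(0))
    meta <- side$meta
  } else {
    fs <- 1 / stats::median(diff(df$time))
    beats <- data.frame(t = numeric(0), sbp = numeric(0), dbp = numeric(0))
    meta <- list()
  }
  structure(list(
    channels = lapply(stats::setNames(REQUIRED_CHANNELS, REQUIRED_CHANNELS),
                      function(nm) df[[nm]]),
    fs = fs,
    bp_beats = beats,
    meta = meta
  ), class = "bp_recording")
}
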