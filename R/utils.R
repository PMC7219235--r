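#' @keywords internal
"_PACKAGE"

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# 32-bit modular multiply; split into 16-bit halves to stay exact in doubles.
mul_mod32 <- function(a, b) {
  lo <- a %% 65536
  hi <- (a - lo) / 65536
  ((hi * b) %% 4294967296 * 65536 + lo * b) %% 4294967296
}

# FNV-1a hash of the JSON encoding of a config object (no digest package in
# the environment); used for pipeline manifests.
config_hash <- function(obj) {
  s <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256  # xor only touches the low byte (b < 256)
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h <- mul_mod32(h, 16777619)
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# Derive a secondary seed (kept below 2^31) so independent RNG streams can be
# used, e.g. beat-level ground truth vs waveform noise.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset) * 48611) %% 2147483629 + 1)
}
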