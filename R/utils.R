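#' @keywords internal
"_PACKAGE"

# Run code under a local RNG state: seeds deterministically, then restores the
# caller's .Random.seed so generators never perturb user-level randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a bounded child seed from a parent seed and a stream index.
# Keeps all derived seeds well below 2^31.
child_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Zero-phase Butterworth band-pass (order 4 each direction via filtfilt).
bp_filter <- function(x, fs, low_hz, high_hz, order = 4) {
  nyq <- fs / 2
  if (!is.null(low_hz) && !is.null(high_hz)) {
    bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  } else if (is.null(low_hz)) {
    bf <- signal::butter(order, high_hz / nyq, type = "low")
  } else {
    bf <- signal::butter(order, low_hz / nyq, type = "high")
  }
  signal::filtfilt(bf, x)
}
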