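#' Re-reference a recording
#'
#' `linked_mastoids` subtracts the mean of the two mastoid/earlobe channels
#' from every channel; `average` subtracts the instantaneous mean over all
#' channels (yielding zero channel-mean at every sample).
#'
#' @param rec An [eeg_recording()].
#' @param scheme `"linked_mastoids"` or `"average"`.
#' @param mastoids Labels of the two reference channels for linked mastoids.
#' @param drop_mastoids Drop the mastoid channels after linked-mastoid
#'   referencing (default TRUE; they are zero-information afterwards up to
#'   their half-difference).
#' @return A re-referenced [eeg_recording()].
#' @export
rereference <- function(rec, scheme = c("linked_mastoids", "average"),
                        mastoids = c("A1", "A2"), drop_mastoids = TRUE) {
  scheme <- match.arg(scheme)
  if (scheme == "linked_mastoids") {
    missing <- setdiff(mastoids, rec$channels)
    if (length(missing) > 0) {
      stopf("missing reference channel(s): %s",
            paste(missing, collapse = ", "))
    }
    idx <- match(mastoids, rec$channels)
    ref <- colMeans(rec$data[idx, , drop = FALSE])
    data <- sweep(rec$data, 2, ref)
    keep <- if (drop_mastoids) setdiff(seq_len(nrow(data)), idx)
            else seq_len(nrow(data))
    eeg_recording(data[keep, , drop = FALSE], rec$fs_hz,
                  rec$channels[keep], rec$annotations)
  } else {
    data <- sweep(rec$data, 2, colMeans(rec$data))
    eeg_recording(data, rec$fs_hz, rec$channels, rec$annotations)
  }
}

#' Band-pass filter and optionally downsample a recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass. When `target_fs` is
#' given, an anti-alias low-pass at 0.4 x `target_fs` is applied (if the
#' band's upper edge does not already provide it) before integer-factor
#' decimation.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Pass-band edges (Hz); `low_hz` may be `NULL` for a
#'   pure low-pass.
#' @param target_fs Output sampling rate (must divide `rec$fs_hz`), or `NULL`
#'   to keep the input rate.
#' @return A filtered [eeg_recording()].
#' @export
bandpass_downsample <- function(rec, low_hz, high_hz, target_fs = NULL) {
  fs <- rec$fs_hz
  nyq_out <- (target_fs %||% fs) / 2
  if (!is.null(low_hz) && low_hz >= high_hz) stopf("invalid band: low >= high")
  if (high_hz >= nyq_out) {
    stopf("high_hz (%g) must be below the output Nyquist (%g)", high_hz,
          nyq_out)
  }
  data <- t(apply(rec$data, 1, bp_filter, fs = fs, low_hz = low_hz,
                  high_hz = high_hz))
  if (!is.null(target_fs)) {
    if (fs %% target_fs != 0) {
      stopf("target_fs must divide fs (%g / %g)", fs, target_fs)
    }
    aa <- 0.4 * target_fs
    if (high_hz > aa) {
      data <- t(apply(data, 1, bp_filter, fs = fs, low_hz = NULL,
                      high_hz = aa))
    }
    dec <- fs %/% target_fs
    # sample at decimation-block centers
    data <- data[, seq(1 + dec %/% 2, ncol(data), by = dec), drop = FALSE]
    ann <- rec$annotations
    return(eeg_recording(data, target_fs, rec$channels, ann))
  }
  eeg_recording(data, fs, rec$channels, rec$annotations)
}

#' Cut one annotated minute into overlapping epochs
#'
#' Tiles the minute with `epoch_s`-second epochs at `(1 - overlap) * epoch_s`
#' hops (default 4 s epochs, 50% overlap, i.e. 2-s hop); a trailing partial
#' window is dropped.
#'
#' @param rec An [eeg_recording()].
#' @param minute Annotation label.
#' @param epoch_s Epoch length in seconds.
#' @param overlap Fractional overlap between consecutive epochs.
#' @return An `eeg_epochs` object: list with `epochs` (list of channels x
#'   length matrices), `starts` (sample indices), `accepted` (logical),
#'   `fs_hz`, `channels`, `minute`.
#' @export
epoch_minute <- function(rec, minute, epoch_s = 4, overlap = 0.5) {
  rng <- annotation_samples(rec, minute)
  fs <- rec$fs_hz
  len <- round(epoch_s * fs)
  hop <- round((1 - overlap) * epoch_s * fs)
  n_avail <- rng["end"] - rng["start"] + 1
  if (n_avail < len) stopf("minute '%s' shorter than one epoch", minute)
  starts <- seq(rng[["start"]], rng[["end"]] - len + 1, by = hop)
  epochs <- lapply(starts, function(s) {
    rec$data[, s:(s + len - 1), drop = FALSE]
  })
  structure(list(epochs = epochs, starts = starts,
                 accepted = rep(TRUE, length(epochs)),
                 fs_hz = fs, channels = rec$channels, minute = minute),
            class = "eeg_epochs")
}

#' Reject epochs on an absolute amplitude criterion
#'
#' An epoch is rejected when any channel sample exceeds `threshold_uV` in
#' absolute value. Idempotent; already-rejected epochs stay rejected.
#'
#' @param eps An `eeg_epochs` object.
#' @param threshold_uV Absolute amplitude threshold (microvolts).
#' @return `eps` with updated `accepted` flags and an `acceptance` attribute
#'   (fraction of accepted epochs).
#' @export
reject_amplitude <- function(eps, threshold_uV = 100) {
  stopifnot(inherits(eps, "eeg_epochs"))
  ok <- vapply(eps$epochs, function(e) all(abs(e) <= threshold_uV), TRUE)
  eps$accepted <- eps$accepted & ok
  attr(eps, "acceptance") <- mean(eps$accepted)
  eps
}

#' Per-minute acceptance table
#'
#' Assembles the percentage of accepted epochs per subject and minute,
#' shaped like a session acceptance summary (one row per subject, one column
#' per minute).
#'
#' @param acceptance Named list per subject of named numeric vectors
#'   (minute -> acceptance fraction).
#' @return Data frame, percentages.
#' @export
acceptance_table <- function(acceptance) {
  minutes <- unique(unlist(lapply(acceptance, names)))
  rows <- lapply(acceptance, function(a) {
    vals <- a[minutes] * 100
    names(vals) <- minutes
    as.data.frame(as.list(vals), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(acceptance)
  out
}

#' Flag subjects whose artifact rejection was excessive
#'
#' A subject is excluded when any analyzed minute has a rejection fraction
#' strictly greater than `max_reject` (a minute at exactly the threshold is
#' retained).
#'
#' @param acceptance Named list per subject of named numeric vectors
#'   (minute -> acceptance fraction in 0..1).
#' @param max_reject Maximum tolerated rejection fraction.
#' @return Character vector of excluded subject names, with a `reasons`
#'   attribute naming the offending minute.
#' @export
exclude_subjects <- function(acceptance, max_reject = 0.75) {
  reasons <- character(0)
  out <- character(0)
  for (s in names(acceptance)) {
    rej <- 1 - acceptance[[s]]
    bad <- which(rej > max_reject)
    if (length(bad) > 0) {
      out <- c(out, s)
      reasons <- c(reasons, sprintf(
        "%s: %.0f%% rejected in minute %s", s, 100 * rej[bad[1]],
        names(rej)[bad[1]]))
    }
  }
  attr(out, "reasons") <- reasons
  out
}
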