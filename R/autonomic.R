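#' Construct an RR-interval series
#'
#' @param rr_ms Inter-beat intervals in milliseconds (all positive).
#' @param time_s Cumulative beat times in seconds (end of each interval,
#'   strictly increasing); derived from `rr_ms` when omitted.
#' @param corrected Logical flags, one per beat (artifact-corrected beats).
#' @return An `rr_series` data frame with columns `time_s`, `rr_ms`,
#'   `corrected`.
#' @export
rr_series <- function(rr_ms, time_s = NULL, corrected = NULL) {
  if (any(rr_ms <= 0)) stopf("all RR intervals must be positive")
  if (is.null(time_s)) time_s <- cumsum(rr_ms) / 1000
  if (any(diff(time_s) <= 0)) stopf("beat times must be strictly increasing")
  structure(data.frame(time_s = time_s, rr_ms = rr_ms,
                       corrected = corrected %||% rep(FALSE, length(rr_ms))),
            class = c("rr_series", "data.frame"))
}

#' Detect R peaks in an ECG signal
#'
#' Adaptive-threshold local-maximum detector with a 250-ms refractory period:
#' candidate samples exceed half the mean of the top-decile amplitudes, are
#' strict local maxima, and successive detections closer than the refractory
#' period keep only the larger peak. The ECG is expected to be band-passed
#' (0.5-35 Hz) beforehand.
#'
#' @param ecg Numeric ECG signal.
#' @param fs Sampling rate (Hz).
#' @param refractory_s Minimum distance between detected peaks (s).
#' @return An `rr_series` derived from successive peak times, with attribute
#'   `peak_times_s`.
#' @export
detect_r_peaks <- function(ecg, fs, refractory_s = 0.25) {
  thr <- 0.5 * stats::quantile(ecg, 0.999, names = FALSE)
  n <- length(ecg)
  i <- 2:(n - 1)
  cand <- i[ecg[i] > ecg[i - 1] & ecg[i] >= ecg[i + 1] & ecg[i] > thr]
  if (length(cand) == 0) stopf("no R peaks found")
  keep <- integer(0)
  last <- -Inf
  for (c0 in cand) {
    if ((c0 - last) / fs >= refractory_s) {
      keep <- c(keep, c0)
      last <- c0
    } else if (ecg[c0] > ecg[keep[length(keep)]]) {
      keep[length(keep)] <- c0
      last <- c0
    }
  }
  if (length(keep) < 2) stopf("fewer than 2 R peaks found")
  times <- (keep - 1) / fs
  out <- rr_series(diff(times) * 1000, time_s = times[-1])
  attr(out, "peak_times_s") <- times
  out
}

#' Flag and correct ectopic / artifactual RR intervals
#'
#' A beat is flagged when its RR deviates more than `max_dev` (fractional)
#' from the running local median (window of `window` beats, the beat itself
#' excluded); flagged values are replaced by linear interpolation from the
#' adjacent unflagged intervals. The fraction corrected is reported (clean
#' recordings in this paradigm run well under 5%); a fraction above 25%
#' raises a hard warning flagging the subject for review.
#'
#' @param rr An `rr_series`.
#' @param max_dev Fractional deviation from the local median that flags a
#'   beat.
#' @param window Local-median window (beats, odd).
#' @return Corrected `rr_series` with `corrected` flags and attribute
#'   `fraction_corrected`.
#' @export
correct_rr_artifacts <- function(rr, max_dev = 0.30, window = 9) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$rr_ms
  n <- length(x)
  half <- window %/% 2
  flag <- logical(n)
  for (i in seq_len(n)) {
    idx <- setdiff(max(1, i - half):min(n, i + half), i)
    med <- stats::median(x[idx])
    flag[i] <- abs(x[i] - med) > max_dev * med
  }
  frac <- mean(flag)
  if (frac > 0.25) {
    warnf("%.0f%% of beats flagged for correction; subject needs review",
          100 * frac)
  }
  if (any(flag)) {
    good <- which(!flag)
    if (length(good) < 2) stopf("too few clean beats to interpolate")
    x[flag] <- stats::approx(good, x[good], xout = which(flag),
                             rule = 2)$y
  }
  out <- rr_series(x, time_s = rr$time_s, corrected = flag | rr$corrected)
  attr(out, "fraction_corrected") <- frac
  out
}

#' Mean heart rate in a time window
#'
#' Mean of instantaneous rates `60000 / RR` over the beats falling in the
#' window; a window with fewer than 2 beats yields a missing value.
#'
#' @param rr An `rr_series`.
#' @param window `c(start_s, end_s)`, half-open.
#' @return Heart rate in beats per minute, or `NA`.
#' @export
heart_rate <- function(rr, window) {
  sel <- rr$time_s >= window[1] & rr$time_s < window[2]
  if (sum(sel) < 2) return(NA_real_)
  mean(60000 / rr$rr_ms[sel])
}

#' High-frequency HRV power in a time window
#'
#' The RR series is linearly interpolated to an evenly sampled 4-Hz series
#' over the window, mean-detrended, and the FFT power spectrum integrated
#' over the HF band (0.15-0.4 Hz). A gap between beats longer than
#' `max_gap_s` inside the window yields a missing value.
#'
#' @param rr An `rr_series`.
#' @param window `c(start_s, end_s)` (typically one minute).
#' @param band HF band in Hz.
#' @param resample_hz Interpolation rate.
#' @param max_gap_s Largest tolerated inter-beat gap inside the window.
#' @return HF power in ms^2, or `NA`.
#' @export
hf_power <- function(rr, window, band = c(0.15, 0.4), resample_hz = 4,
                     max_gap_s = 5) {
  sel <- rr$time_s >= window[1] & rr$time_s < window[2]
  if (sum(sel) < 4) return(NA_real_)
  tt <- rr$time_s[sel]
  if (max(diff(c(window[1], tt, window[2]))) > max_gap_s) return(NA_real_)
  grid <- seq(window[1], window[2], by = 1 / resample_hz)
  x <- stats::approx(tt, rr$rr_ms[sel], xout = grid, rule = 2)$y
  x <- x - mean(x)
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * resample_hz / n
  inb <- f >= band[1] & f <= band[2]
  sum(2 * Mod(X[inb])^2 / n^2)
}

#' Percent deviation from a reference mean
#'
#' `100 * (v - reference) / reference` per value; by construction the
#' transformed values average to zero over the reference period when the
#' reference is their mean.
#'
#' @param values Numeric vector (e.g. per-minute HF power).
#' @param reference Reference level; defaults to `mean(values, na.rm=TRUE)`.
#' @return Transformed vector (percent).
#' @export
percent_deviation <- function(values, reference = NULL) {
  reference <- reference %||% mean(values, na.rm = TRUE)
  if (!is.finite(reference) || reference == 0) {
    stopf("percent deviation undefined for zero reference")
  }
  100 * (values - reference) / reference
}

#' Range-corrected skin conductance level for a window
#'
#' `corrected = (mean - min) / (max - min)` over the window, correcting for
#' individual differences in absolute conductance; invariant to affine
#' rescaling of the trace. A flat window (max = min) yields a missing value.
#'
#' @param trace An `scl_trace` (data frame `time_s`, `uS`).
#' @param window `c(start_s, end_s)`, half-open.
#' @return Corrected SCL in 0..1, or `NA` for a flat window.
#' @export
scl_minute_corrected <- function(trace, window) {
  sel <- trace$time_s >= window[1] & trace$time_s < window[2]
  if (!any(sel)) return(NA_real_)
  x <- trace$uS[sel]
  rng <- range(x)
  if (diff(rng) < .Machine$double.eps) return(NA_real_)
  (mean(x) - rng[1]) / diff(rng)
}

#' Baseline-subtracted response values and focus-phase means
#'
#' Subtracts the averaged baseline from each minute's value and averages the
#' responses over the other-focus (LKM 1-5) and self-focus (LKM 6-11)
#' minutes.
#'
#' @param minute_values Named numeric vector, names are minute labels
#'   (`LKM1` ... and optionally others).
#' @param baseline Averaged baseline value (e.g. the mean of four 1-min
#'   pre-induction blocks); `NA` baseline is an error (the subject is
#'   excluded upstream).
#' @return List: `response` (named vector), `other_mean`, `self_mean`.
#' @export
response_values <- function(minute_values, baseline) {
  if (is.null(baseline) || is.na(baseline)) {
    stopf("missing baseline: subject must be excluded for this measure")
  }
  resp <- minute_values - baseline
  idx <- suppressWarnings(as.integer(sub("^LKM", "", names(resp))))
  list(response = resp,
       other_mean = mean(resp[!is.na(idx) & idx <= 5], na.rm = TRUE),
       self_mean = mean(resp[!is.na(idx) & idx >= 6], na.rm = TRUE))
}

#' Per-minute autonomic measures for one subject's session
#'
#' Computes HR, HF-HRV and range-corrected SCL per annotated minute, the
#' percent-deviation transform for HF power (reference = all analyzed
#' minutes), and baseline-subtracted responses. The baseline value is the
#' measure at the `B` minute (or the mean over several baseline blocks when
#' multiple `B*` labels are annotated).
#'
#' @param rr An `rr_series` covering the session.
#' @param scl An `scl_trace` covering the session.
#' @param minutes Data frame `label`, `start_s`, `end_s` (half-open).
#' @return Data frame: `minute`, `hr_bpm`, `hf_ms2`, `hrv_pct`,
#'   `scl_corrected`, plus `*_response` columns, with focus-phase means in
#'   the `phase_means` attribute.
#' @export
autonomic_timecourse <- function(rr, scl, minutes) {
  vals <- lapply(seq_len(nrow(minutes)), function(i) {
    w <- c(minutes$start_s[i], minutes$end_s[i])
    data.frame(minute = minutes$label[i],
               hr_bpm = heart_rate(rr, w),
               hf_ms2 = hf_power(rr, w),
               scl_corrected = scl_minute_corrected(scl, w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, vals)
  out$hrv_pct <- percent_deviation(out$hf_ms2)
  is_base <- grepl("^B", out$minute)
  base_of <- function(col) mean(out[[col]][is_base], na.rm = TRUE)
  nm <- stats::setNames(seq_len(nrow(out)), out$minute)
  pm <- list()
  for (col in c("hr_bpm", "hrv_pct", "scl_corrected")) {
    rv <- response_values(stats::setNames(out[[col]], out$minute),
                          base_of(col))
    out[[paste0(col, "_response")]] <- rv$response
    pm[[col]] <- c(other = rv$other_mean, self = rv$self_mean)
  }
  attr(out, "phase_means") <- pm
  out
}
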