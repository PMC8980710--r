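#' Configuration for the synthetic autonomic generators
#'
#' Parameters of the RR-interval and skin-conductance generators. The RR
#' series carries a sinusoidal high-frequency (respiratory-band) modulation so
#' HF-HRV estimation has a closed-form oracle; the SCL trace is a linear
#' drift plus exponential-recovery arousal events locked to given minutes.
#'
#' @param mean_hr_bpm Mean heart rate (beats per minute), in (30, 200).
#' @param hf_mod_freq_hz Frequency of the sinusoidal RR modulation (Hz);
#'   0.15-0.4 Hz lies inside the HF-HRV band.
#' @param hf_mod_depth_ms Amplitude of the RR modulation (ms).
#' @param rr_noise_ms SD of white RR noise (ms).
#' @param scl_baseline_uS Tonic skin conductance level (microsiemens), >= 0.
#' @param scl_event_minutes 1-based minutes at whose onset an arousal event
#'   starts.
#' @param scl_event_amplitude_uS Event amplitude (microsiemens).
#' @param scl_event_tau_s Exponential recovery time constant (s).
#' @param scl_drift_uS_per_min Linear drift of the tonic level.
#' @param scl_noise_uS SD of measurement noise on the SCL trace.
#' @param scl_fs_hz SCL sampling rate (Hz).
#' @return An `autonomic_gen_config` list, validated.
#' @export
autonomic_gen_config <- function(mean_hr_bpm = 70,
                                 hf_mod_freq_hz = 0.25,
                                 hf_mod_depth_ms = 30,
                                 rr_noise_ms = 10,
                                 scl_baseline_uS = 5,
                                 scl_event_minutes = c(1, 7),
                                 scl_event_amplitude_uS = 0.8,
                                 scl_event_tau_s = 25,
                                 scl_drift_uS_per_min = -0.02,
                                 scl_noise_uS = 0.01,
                                 scl_fs_hz = 50) {
  if (mean_hr_bpm <= 30 || mean_hr_bpm >= 200) {
    stopf("mean_hr_bpm must be in (30, 200)")
  }
  if (scl_baseline_uS < 0) stopf("scl_baseline_uS must be non-negative")
  structure(as.list(environment()), class = "autonomic_gen_config")
}

#' Generate a synthetic RR-interval series
#'
#' `RR_i = 60000 / mean_hr_bpm + hf_mod_depth_ms * sin(2*pi*f*t_i) + noise`,
#' with cumulative beat times covering `n_minutes` minutes.
#'
#' @param cfg An [autonomic_gen_config()].
#' @param n_minutes Minutes to cover.
#' @param seed Integer seed.
#' @return An `rr_series`: data frame with `time_s` (beat time at the end of
#'   each interval) and `rr_ms`, plus a `ground_truth` attribute.
#' @export
generate_rr_series <- function(cfg, n_minutes, seed) {
  stopifnot(inherits(cfg, "autonomic_gen_config"))
  with_seed(seed, {
    base <- 60000 / cfg$mean_hr_bpm
    total_s <- n_minutes * 60
    t <- 0
    times <- numeric(0)
    rr <- numeric(0)
    while (t < total_s) {
      r <- base + cfg$hf_mod_depth_ms * sin(2 * pi * cfg$hf_mod_freq_hz * t) +
        stats::rnorm(1, sd = cfg$rr_noise_ms)
      if (r <= 0) {
        stopf("non-positive RR interval generated; reduce depth or noise")
      }
      t <- t + r / 1000
      times <- c(times, t)
      rr <- c(rr, r)
    }
    out <- rr_series(rr, times)
    attr(out, "ground_truth") <- list(
      base_rr_ms = base, hf_mod_freq_hz = cfg$hf_mod_freq_hz,
      hf_mod_depth_ms = cfg$hf_mod_depth_ms, n_beats = length(rr),
      seed = seed)
    out
  })
}

#' Generate a synthetic skin conductance trace
#'
#' Tonic baseline with linear drift, exponential-recovery arousal events at
#' the onsets of `scl_event_minutes`, and white measurement noise; the trace
#' is clipped at zero (conductance is non-negative).
#'
#' @inheritParams generate_rr_series
#' @return An `scl_trace`: data frame with `time_s` and `uS`; attribute
#'   `ground_truth`.
#' @export
generate_scl_trace <- function(cfg, n_minutes, seed) {
  stopifnot(inherits(cfg, "autonomic_gen_config"))
  with_seed(seed, {
    fs <- cfg$scl_fs_hz
    n <- n_minutes * 60 * fs
    t <- (seq_len(n) - 1) / fs
    x <- cfg$scl_baseline_uS + cfg$scl_drift_uS_per_min * t / 60
    for (m in cfg$scl_event_minutes) {
      t0 <- (m - 1) * 60
      on <- t >= t0
      x[on] <- x[on] + cfg$scl_event_amplitude_uS *
        exp(-(t[on] - t0) / cfg$scl_event_tau_s)
    }
    if (cfg$scl_noise_uS > 0) x <- x + stats::rnorm(n, sd = cfg$scl_noise_uS)
    x <- pmax(x, 0)
    out <- structure(data.frame(time_s = t, uS = x), class =
                       c("scl_trace", "data.frame"))
    attr(out, "ground_truth") <- list(
      event_minutes = cfg$scl_event_minutes,
      event_amplitude_uS = cfg$scl_event_amplitude_uS, seed = seed)
    out
  })
}

# Synthetic ECG: Gaussian QRS-like template train at given beat times.
# Used to exercise the R-peak detector against planted beat positions.
synthetic_ecg <- function(beat_times_s, fs = 500, duration_s = NULL,
                          amp_mV = 1, width_s = 0.02, noise_mV = 0.02,
                          seed = NULL) {
  with_seed(seed, {
    duration_s <- duration_s %||% (max(beat_times_s) + 1)
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    x <- numeric(n)
    for (bt in beat_times_s) {
      idx <- which(abs(t - bt) < 5 * width_s)
      x[idx] <- x[idx] + amp_mV * exp(-((t[idx] - bt)^2) / (2 * width_s^2))
    }
    if (noise_mV > 0) x <- x + stats::rnorm(n, sd = noise_mV)
    structure(list(signal = x, fs_hz = fs, beat_times_s = beat_times_s),
              class = "synthetic_ecg")
  })
}
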