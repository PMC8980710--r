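#' Configuration for the synthetic microstate EEG generator
#'
#' Defines the generative model for one subject's EEG: a hidden microstate
#' sequence (geometric run lengths at the analysis rate, transitions from a
#' row-stochastic matrix with zero diagonal), each state expressed as a fixed
#' unit-norm topography multiplied by a polarity-alternating arc carrier that
#' passes through zero at every state transition (so transitions sit at GFP
#' minima and consecutive GFP peaks share a potential shape with reversed
#' polarity, as in resting EEG);
#' plus alpha-band (8-13 Hz) oscillations on the asymmetry-cluster electrodes
#' with an exactly injected ln(right/left) power offset per region; plus white
#' sensor noise at a configurable map-signal-to-noise ratio.
#'
#' @param channels Channel labels; must contain all 20 asymmetry-cluster
#'   electrodes (error names the first missing one).
#' @param fs_hz Sampling rate (Hz); must be a multiple of `state_fs_hz`.
#' @param state_fs_hz Rate (Hz) at which the hidden state sequence is defined;
#'   125 Hz matches the microstate analysis rate so realized run lengths are
#'   commensurate with the estimator grid.
#' @param true_maps k x n_channels matrix of unit-norm topographies (rows);
#'   default: the four canonical templates.
#' @param mean_durations_ms Target mean microstate duration per state: a
#'   length-k vector, or a k x n_minutes matrix for per-minute targets.
#' @param lkm_boost_ms Length-k vector added to the duration targets in
#'   minutes labelled `LKM*` (planted induction effect; default zeros).
#' @param transition_matrix k x k row-stochastic matrix, zero diagonal
#'   (self-transitions are expressed through run lengths). Default: uniform.
#' @param alpha_asym_log_offset Named vector `c(anterior=, posterior=)`:
#'   injected ln(right/left) alpha power offset per region.
#' @param alpha_rms_uV RMS amplitude of the alpha oscillation on each left
#'   cluster channel (microvolts).
#' @param map_rms_uV Per-channel RMS of the microstate map component over
#'   scalp channels.
#' @param snr_db Map-signal-to-noise ratio in dB: mean per-channel map-signal
#'   power over white-noise variance. `Inf` disables noise.
#' @return An `eeg_gen_config` list, validated.
#' @export
eeg_gen_config <- function(channels = default_montage(),
                           fs_hz = 500,
                           state_fs_hz = 125,
                           true_maps = canonical_templates(channels),
                           mean_durations_ms = c(A = 40, B = 60,
                                                 C = 80, D = 100),
                           lkm_boost_ms = NULL,
                           transition_matrix = NULL,
                           alpha_asym_log_offset = c(anterior = 0,
                                                     posterior = 0),
                           alpha_rms_uV = 10,
                           map_rms_uV = 10,
                           snr_db = 5) {
  need <- unlist(asymmetry_clusters(), use.names = FALSE)
  missing <- setdiff(need, channels)
  if (length(missing) > 0) {
    stopf("channel list is missing required asymmetry electrode '%s'",
          missing[1])
  }
  if (fs_hz %% state_fs_hz != 0) {
    stopf("fs_hz (%g) must be a multiple of state_fs_hz (%g)",
          fs_hz, state_fs_hz)
  }
  true_maps <- as.matrix(true_maps)
  k <- nrow(true_maps)
  if (ncol(true_maps) != length(channels)) {
    stopf("true_maps has %d columns but %d channels", ncol(true_maps),
          length(channels))
  }
  norms <- sqrt(rowSums(true_maps^2))
  if (any(abs(norms - 1) > 1e-9)) stopf("true_maps rows must have unit norm")
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / max(k - 1, 1), k, k)
    diag(transition_matrix) <- 0
    if (k == 1) transition_matrix <- matrix(0, 1, 1)
  }
  if (k > 1) {
    if (any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
      stopf("transition_matrix rows must sum to 1")
    }
    if (any(abs(diag(transition_matrix)) > 0)) {
      stopf("transition_matrix diagonal must be 0")
    }
  }
  if (is.null(lkm_boost_ms)) lkm_boost_ms <- numeric(k)
  structure(
    list(channels = channels, fs_hz = fs_hz, state_fs_hz = state_fs_hz,
         true_maps = true_maps, k = k,
         mean_durations_ms = mean_durations_ms, lkm_boost_ms = lkm_boost_ms,
         transition_matrix = transition_matrix,
         alpha_asym_log_offset = alpha_asym_log_offset,
         alpha_rms_uV = alpha_rms_uV, map_rms_uV = map_rms_uV,
         snr_db = snr_db),
    class = "eeg_gen_config")
}

# Markov run-length state sequence for one minute at the state rate.
# Run lengths are geometric with a 2-sample (16 ms at 125 Hz) minimum and
# the requested mean: sub-resolution single-sample states cannot be carried
# by a 1-30 Hz field and are not observed in practice. Returns integer
# states of length n_state.
simulate_state_minute <- function(k, mean_samples, trans, n_state,
                                  start_state) {
  if (k == 1) return(rep(1L, n_state))
  states <- integer(n_state)
  pos <- 1L
  s <- start_state
  while (pos <= n_state) {
    mu <- max(mean_samples[s], 2.5)
    len <- stats::rgeom(1, prob = 1 / (mu - 1)) + 2L
    end <- min(pos + len - 1L, n_state)
    states[pos:end] <- s
    pos <- end + 1L
    s <- sample.int(k, 1, prob = trans[s, ])
  }
  states
}

# Oscillatory map carrier. Each microstate run is expressed as a beta-band
# (fs/24 Hz, ~21 Hz at 500 Hz) cosine inside a flat-topped per-run window
# that ramps to zero at the run edges. This mirrors the phenomenology
# microstate analysis is built on: the scalp field oscillates under a
# quasi-stable topography, transitions sit at field minima, and consecutive
# GFP peaks carry the same potential shape with reversed polarity. The
# windowed oscillation has no DC content (so the 1-Hz edge of the 1-30 Hz
# analysis band-pass does not hollow out long runs), passes through zero at
# every state transition (no smearing of one state's field into the next),
# and its zero crossings are phase-locked between the samples of the
# 4-to-1 decimation grid, so every analyzed sample carries at least half
# the carrier amplitude. A slow log-normal gain varies GFP peak height.
state_carrier <- function(state_seq_hi, fs, rms, ramp_samples = 4,
                          gain_lp_hz = 0.7, gain_log_sd = 0.25) {
  r <- rle(state_seq_hi)
  n <- length(state_seq_hi)
  w <- numeric(n)
  pos <- 1L
  for (L in r$lengths) {
    win <- rep(1, L)
    tw <- min(ramp_samples, L %/% 2)
    if (tw > 0) {
      ramp <- sin(seq_len(tw) / (tw + 1) * pi / 2)^2
      win[seq_len(tw)] <- ramp
      win[(L - tw + 1):L] <- rev(ramp)
    }
    w[pos:(pos + L - 1L)] <- win
    pos <- pos + L
  }
  osc <- cos(pi * (seq_len(n) + 1) / 12)
  u <- bp_filter(stats::rnorm(n), fs, NULL, gain_lp_hz)
  gain <- exp(gain_log_sd * u / stats::sd(u))
  out <- w * osc * gain
  out * rms / sqrt(mean(out^2))
}

#' Generate one subject's synthetic microstate EEG
#'
#' Produces a continuous recording whose every sample is
#' `active-state topography x amplitude envelope + alpha oscillation + white
#' noise`, with one annotated minute per entry of `labels`. The attached
#' `ground_truth` attribute carries the realized hidden state sequence (at the
#' state rate), the realized per-minute mean durations, the injected
#' asymmetry offsets, and the realized per-channel variance of the noise-free
#' alpha component (so the injected ln(R/L) offset can be checked by direct
#' band-power computation).
#'
#' @param cfg An [eeg_gen_config()].
#' @param n_minutes Number of annotated 60-s minutes.
#' @param seed Integer seed; the same seed reproduces the recording exactly.
#' @param labels Minute labels; default `B`, `LKM1`, `LKM2`, ... Duration
#'   boosts (`lkm_boost_ms`) apply to minutes whose label starts with "LKM".
#' @return An [eeg_recording()] with attribute `ground_truth`.
#' @export
generate_microstate_eeg <- function(cfg, n_minutes, seed, labels = NULL) {
  stopifnot(inherits(cfg, "eeg_gen_config"))
  if (is.null(labels)) {
    labels <- c("B", if (n_minutes > 1) paste0("LKM", seq_len(n_minutes - 1)))
  }
  stopifnot(length(labels) == n_minutes)
  with_seed(seed, {
    fs <- cfg$fs_hz
    k <- cfg$k
    up <- fs %/% cfg$state_fs_hz
    n_state_min <- 60 * cfg$state_fs_hz
    n_min <- 60 * fs
    n_ch <- length(cfg$channels)

    # duration targets per minute (k x n_minutes)
    tgt <- cfg$mean_durations_ms
    if (is.matrix(tgt)) {
      stopifnot(nrow(tgt) == k, ncol(tgt) == n_minutes)
    } else {
      tgt <- matrix(tgt, nrow = k, ncol = n_minutes)
    }
    dimnames(tgt) <- list(rownames(cfg$true_maps) %||%
                            as.character(seq_len(k)), labels)
    is_lkm <- grepl("^LKM", labels)
    tgt[, is_lkm] <- tgt[, is_lkm] + cfg$lkm_boost_ms

    state_seq <- integer(0)
    realized <- matrix(NA_real_, k, n_minutes,
                       dimnames = list(rownames(cfg$true_maps) %||%
                                         as.character(seq_len(k)), labels))
    s0 <- sample.int(k, 1)
    for (m in seq_len(n_minutes)) {
      mean_samples <- tgt[, m] / 1000 * cfg$state_fs_hz
      sm <- simulate_state_minute(k, mean_samples, cfg$transition_matrix,
                                  n_state_min, s0)
      s0 <- if (k > 1) {
        sample.int(k, 1, prob = cfg$transition_matrix[sm[n_state_min], ])
      } else 1L
      r <- rle(sm)
      for (s in seq_len(k)) {
        if (any(r$values == s)) {
          realized[s, m] <- mean(r$lengths[r$values == s]) *
            1000 / cfg$state_fs_hz
        }
      }
      state_seq <- c(state_seq, sm)
    }

    n <- n_minutes * n_min
    state_500 <- rep(state_seq, each = up)

    env_rms <- cfg$map_rms_uV * sqrt(n_ch)
    env <- state_carrier(state_500, fs, env_rms)
    data <- t(cfg$true_maps)[, state_500, drop = FALSE] *
      rep(env, each = n_ch)

    # alpha with exact hemispheric log-power offset: right channel is a
    # scaled copy of its left homologue, so ln(P_R/P_L) = offset exactly.
    alpha_var <- stats::setNames(numeric(n_ch), cfg$channels)
    pairs <- cluster_pairs()
    for (region in names(pairs)) {
      off <- cfg$alpha_asym_log_offset[[region]]
      pr <- pairs[[region]]
      for (j in seq_len(nrow(pr))) {
        base <- bp_filter(stats::rnorm(n), fs, 8, 13)
        base <- base * cfg$alpha_rms_uV / stats::sd(base)
        li <- match(pr[j, "left"], cfg$channels)
        ri <- match(pr[j, "right"], cfg$channels)
        left_sig <- base
        right_sig <- base * exp(off / 2)
        data[li, ] <- data[li, ] + left_sig
        data[ri, ] <- data[ri, ] + right_sig
        alpha_var[li] <- mean(left_sig^2)
        alpha_var[ri] <- mean(right_sig^2)
      }
    }

    if (is.finite(cfg$snr_db)) {
      sigma <- cfg$map_rms_uV * 10^(-cfg$snr_db / 20)
      data <- data + matrix(stats::rnorm(n_ch * n, sd = sigma), n_ch, n)
    }

    ann <- data.frame(label = labels,
                      start_s = (seq_len(n_minutes) - 1) * 60,
                      end_s = seq_len(n_minutes) * 60,
                      stringsAsFactors = FALSE)
    rec <- eeg_recording(data, fs, cfg$channels, ann)
    attr(rec, "ground_truth") <- list(
      state_seq = state_seq,
      state_fs_hz = cfg$state_fs_hz,
      realized_durations_ms = realized,
      target_durations_ms = tgt,
      alpha_asym_log_offset = cfg$alpha_asym_log_offset,
      alpha_channel_var = alpha_var,
      seed = seed
    )
    rec
  })
}
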