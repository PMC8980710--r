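#' Per-channel power spectrum of one accepted epoch
#'
#' Hamming-windowed FFT over the distal half of the epoch (the final 2 s of a
#' 4-s epoch), giving 0.5-Hz bins with no zero padding. Bin powers are
#' window-normalized so that a unit-amplitude sinusoid contributes total band
#' power 1/2 (amplitude^2 / 2): `P_k = 2|X_k|^2 / (N * sum(w^2))`.
#'
#' @param epoch Channels x samples matrix (one epoch).
#' @param fs Sampling rate (Hz).
#' @param accepted Logical; passing a rejected epoch is an error.
#' @param distal_frac Fraction of the epoch tail used (default 0.5).
#' @return Channels x bins matrix of bin powers (microvolt^2 per bin) with
#'   attribute `freq_hz`; divide by the 0.5-Hz bin width for densities.
#' @export
epoch_psd <- function(epoch, fs, accepted = TRUE, distal_frac = 0.5) {
  if (!accepted) stopf("rejected epoch passed to epoch_psd")
  n_total <- ncol(epoch)
  n <- round(n_total * distal_frac)
  seg <- epoch[, (n_total - n + 1):n_total, drop = FALSE]
  w <- signal::hamming(n)
  sw2 <- sum(w^2)
  nk <- n %/% 2 + 1
  pw <- t(apply(seg, 1, function(x) {
    X <- stats::fft(x * w)[seq_len(nk)]
    p <- 2 * Mod(X)^2 / (n * sw2)
    p[1] <- p[1] / 2                       # DC is not doubled
    if (n %% 2 == 0) p[nk] <- p[nk] / 2    # nor Nyquist
    p
  }))
  attr(pw, "freq_hz") <- (seq_len(nk) - 1) * fs / n
  rownames(pw) <- rownames(epoch)
  pw
}

#' Alpha-band power density for one minute
#'
#' Averages per-bin powers across accepted epochs, then across the band's
#' 0.5-Hz bins, returning a per-channel power density in microvolt^2/Hz. A
#' minute with zero accepted epochs is marked missing (`NULL`), never zero.
#'
#' @param eps An `eeg_epochs` object (after [reject_amplitude()]).
#' @param band Frequency band in Hz (inclusive bin range, default 8-13).
#' @return A `band_power` list: `density` (named per-channel, microvolt^2/Hz),
#'   `minute`, `n_epochs`; or `NULL` when no epoch was accepted.
#' @export
minute_band_power <- function(eps, band = c(8, 13)) {
  stopifnot(inherits(eps, "eeg_epochs"))
  keep <- which(eps$accepted)
  if (length(keep) == 0) return(NULL)
  acc <- NULL
  for (i in keep) {
    pw <- epoch_psd(eps$epochs[[i]], eps$fs_hz)
    acc <- if (is.null(acc)) pw else acc + pw
  }
  pw_mean <- acc / length(keep)
  f <- attr(acc, "freq_hz")
  bins <- f >= band[1] - 1e-9 & f <= band[2] + 1e-9
  bin_width <- f[2] - f[1]
  density <- rowMeans(pw_mean[, bins, drop = FALSE]) / bin_width
  structure(list(density = stats::setNames(density, eps$channels),
                 minute = eps$minute, n_epochs = length(keep)),
            class = "band_power")
}

#' Hemispheric asymmetry score from band power
#'
#' `ln(mean right-cluster density) - ln(mean left-cluster density)`:
#' channel densities are averaged within each cluster first, then
#' log-transformed (natural log). Positive values mean more right-hemisphere
#' alpha power.
#'
#' @param bp A `band_power` from [minute_band_power()].
#' @param region `"anterior"` or `"posterior"`.
#' @param clusters Electrode clusters (default [asymmetry_clusters()]).
#' @return An `asymmetry_score` list: `region`, `value`, `minute`.
#' @export
asymmetry <- function(bp, region = c("anterior", "posterior"),
                      clusters = asymmetry_clusters()) {
  region <- match.arg(region)
  stopifnot(inherits(bp, "band_power"))
  left <- clusters[[paste0(region, "_left")]]
  right <- clusters[[paste0(region, "_right")]]
  missing <- setdiff(c(left, right), names(bp$density))
  if (length(missing) > 0) {
    stopf("band power lacks cluster channel(s): %s",
          paste(missing, collapse = ", "))
  }
  ml <- mean(bp$density[left])
  mr <- mean(bp$density[right])
  if (ml <= 0 || mr <= 0) stopf("non-positive cluster mean power")
  structure(list(region = region, value = log(mr) - log(ml),
                 minute = bp$minute), class = "asymmetry_score")
}

#' Per-minute asymmetry time course and focus-phase means for one subject
#'
#' Runs the asymmetry chain on every annotated minute: linked-mastoid
#' re-referencing (when the mastoid channels are present), 1-40 Hz band-pass,
#' 4-s epochs with 50% overlap, +/-100 uV rejection, Hamming PSD on the
#' distal halves, cluster band power, ln(R) - ln(L). Focus-phase means are
#' the averages over the other-focus minutes (LKM 1-5) and self-focus minutes
#' (LKM 6-11), over whatever minutes are available and not excluded.
#'
#' @param rec An [eeg_recording()] with minute annotations.
#' @param exclude_minutes Minutes dropped from the EEG analysis (default
#'   `"LKM1"`).
#' @param band Alpha band (Hz).
#' @param threshold_uV Epoch rejection threshold.
#' @param prefilter Band-pass applied before epoching (`c(low, high)` in Hz)
#'   or `NULL` to skip.
#' @return List with `scores` (data frame minute x region x value),
#'   `phase_means` (data frame region x other/self), `n_minutes_used`.
#' @export
asymmetry_timecourse <- function(rec, exclude_minutes = "LKM1",
                                 band = c(8, 13), threshold_uV = 100,
                                 prefilter = c(1, 40)) {
  if (all(c("A1", "A2") %in% rec$channels)) {
    rec <- rereference(rec, "linked_mastoids")
  }
  if (!is.null(prefilter)) {
    rec <- bandpass_downsample(rec, prefilter[1], prefilter[2])
  }
  minutes <- setdiff(rec$annotations$label, exclude_minutes)
  rows <- list()
  for (m in minutes) {
    eps <- reject_amplitude(epoch_minute(rec, m), threshold_uV)
    bp <- minute_band_power(eps, band = band)
    for (region in c("anterior", "posterior")) {
      val <- if (is.null(bp)) NA_real_ else asymmetry(bp, region)$value
      rows[[length(rows) + 1]] <- data.frame(
        minute = m, region = region, value = val,
        stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, rows)
  lkm_idx <- function(lbl) suppressWarnings(as.integer(sub("^LKM", "", lbl)))
  phase_of <- function(lbl) {
    i <- lkm_idx(lbl)
    ifelse(is.na(i), NA_character_, ifelse(i <= 5, "other", "self"))
  }
  scores$phase <- phase_of(scores$minute)
  pm <- do.call(rbind, lapply(c("anterior", "posterior"), function(rg) {
    sub <- scores[scores$region == rg & !is.na(scores$phase), ]
    data.frame(
      region = rg,
      other = mean(sub$value[sub$phase == "other"], na.rm = TRUE),
      self = mean(sub$value[sub$phase == "self"], na.rm = TRUE),
      n_other = sum(sub$phase == "other" & !is.na(sub$value)),
      n_self = sum(sub$phase == "self" & !is.na(sub$value)),
      stringsAsFactors = FALSE)
  }))
  list(scores = scores, phase_means = pm,
       n_minutes_used = sum(!is.na(scores$value)) / 2)
}
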