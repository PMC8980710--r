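# Microstate segmentation: GFP peaks, polarity-invariant modified k-means,
# canonical A-D labeling, winner-takes-all backfitting, duration statistics.
# All topographic operations assume average-referenced data; spatial
# correlation is the Pearson correlation across channels, whose absolute
# value makes every step polarity-invariant.

# Pearson spatial correlation of data columns (channels x time) against map
# rows (k x channels). Returns time x k matrix. Zero-variance columns give 0.
spatial_corr <- function(data, maps) {
  nc <- nrow(data)
  dc <- sweep(data, 2, colMeans(data))
  dn <- sqrt(colSums(dc^2))
  mc <- maps - rowMeans(maps)
  mn <- sqrt(rowSums(mc^2))
  num <- t(dc) %*% t(mc)
  den <- outer(dn, mn)
  out <- num / den
  out[den == 0] <- 0
  out
}

#' Global field power
#'
#' Per-sample population standard deviation of the potential across all
#' channels. Peaks of the GFP index the high signal-to-noise topographies the
#' segmentation is built from.
#'
#' @param rec An [eeg_recording()] (average-referenced for topographic use).
#' @return Numeric vector, one value per sample, with attribute `fs_hz`.
#' @export
gfp <- function(rec) {
  if (nrow(rec$data) < 2) stopf("GFP requires at least 2 channels")
  m <- colMeans(rec$data)
  g <- sqrt(colMeans(rec$data^2) - m^2)
  g[g < 0 | is.na(g)] <- 0
  attr(g, "fs_hz") <- rec$fs_hz
  g
}

#' Indices of strict local maxima of a GFP series
#'
#' A peak satisfies `g[i-1] < g[i] > g[i+1]`; endpoints are never peaks.
#'
#' @param g Numeric GFP series.
#' @return Integer vector of peak indices (possibly empty).
#' @export
gfp_peaks <- function(g) {
  n <- length(g)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[g[i] > g[i - 1] & g[i] > g[i + 1]]
}

#' Sample unit-norm topographies at the strongest GFP peaks
#'
#' Selects the `n` peaks of highest GFP (all peaks, with a warning, if fewer
#' are available) and returns their average-referenced, unit-norm
#' topographies.
#'
#' @param rec Average-referenced [eeg_recording()].
#' @param peaks Peak sample indices (from [gfp_peaks()]).
#' @param n Number of peak maps to keep.
#' @param method `"top_gfp"` (default: the n highest-GFP peaks) or
#'   `"uniform"` (every floor(length/n)-th peak).
#' @return Maps matrix (n x channels, unit-norm rows) with attribute
#'   `gfp` (the peaks' GFP values, used as weights in the fit).
#' @export
sample_peak_maps <- function(rec, peaks, n = 100,
                             method = c("top_gfp", "uniform")) {
  method <- match.arg(method)
  if (length(peaks) == 0) stopf("no GFP peaks available")
  g <- gfp(rec)
  if (length(peaks) > n) {
    sel <- switch(method,
      top_gfp = peaks[order(g[peaks], decreasing = TRUE)[seq_len(n)]],
      uniform = peaks[round(seq(1, length(peaks), length.out = n))])
  } else {
    if (length(peaks) < n) {
      warnf("only %d GFP peaks available (requested %d)", length(peaks), n)
    }
    sel <- peaks
  }
  maps <- t(rec$data[, sel, drop = FALSE])
  maps <- maps - rowMeans(maps)
  norms <- sqrt(rowSums(maps^2))
  maps <- maps / norms
  colnames(maps) <- rec$channels
  attr(maps, "gfp") <- g[sel]
  maps
}

# GEV of prototypes on maps with weights w: sum((w * |corr|)^2) / sum(w^2).
gev_of <- function(maps, protos, w) {
  corr <- spatial_corr(t(maps), protos)
  best <- apply(abs(corr), 1, max)
  sum((w * best)^2) / sum(w^2)
}

#' Polarity-invariant modified k-means over peak maps
#'
#' Iteratively assigns each map to the prototype maximizing the squared
#' spatial correlation (so a map and its polarity reversal are equivalent)
#' and updates each prototype as the dominant eigenvector of the sum of outer
#' products of its assigned maps. Convergence is declared when the assignment
#' is stable or the relative change in global explained variance (GEV) falls
#' below `tol`. The best of `n_restarts` random initializations by GEV is
#' kept; results are deterministic given `seed`.
#'
#' @param maps n x channels matrix of unit-norm, average-referenced maps
#'   (typically from [sample_peak_maps()]); an attached `gfp` attribute is
#'   used as GEV weights (unit weights otherwise).
#' @param k Number of microstate classes.
#' @param n_restarts Random restarts.
#' @param seed Integer seed.
#' @param max_iter Iteration cap per restart.
#' @param tol Relative GEV convergence tolerance.
#' @return A `microstate_model`: `maps` (k x channels, unit norm), `labels`
#'   (map names; indices until canonical alignment), `gev`, `k`, `channels`,
#'   and fit metadata (`n_restarts`, `seed`, `iterations`).
#' @export
modified_kmeans <- function(maps, k, n_restarts = 50, seed = 1,
                            max_iter = 100, tol = 1e-6) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < k) stopf("need at least k = %d maps, got %d", k, n)
  w <- attr(maps, "gfp") %||% rep(1, n)
  mc <- maps - rowMeans(maps)     # spatial means removed once, up front
  mc <- mc / sqrt(rowSums(mc^2))
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      protos <- mc[sample.int(n, k), , drop = FALSE]
      assign_prev <- integer(n)
      gev_prev <- -Inf
      iters <- 0L
      for (it in seq_len(max_iter)) {
        iters <- it
        corr <- mc %*% t(protos)   # rows unit-norm & centered: plain product
        a <- max.col(corr^2, ties.method = "first")
        # empty cluster: reseed from the worst-fitted map
        fit <- abs(corr[cbind(seq_len(n), a)])
        for (s in seq_len(k)) {
          if (!any(a == s)) {
            a[which.min(fit)] <- s
            fit[which.min(fit)] <- 1
          }
        }
        for (s in seq_len(k)) {
          sub <- mc[a == s, , drop = FALSE]
          v <- svd(sub, nu = 0, nv = 1)$v[, 1]
          protos[s, ] <- v / sqrt(sum(v^2))
        }
        g <- {
          corr <- mc %*% t(protos)
          bestc <- apply(abs(corr), 1, max)
          sum((w * bestc)^2) / sum(w^2)
        }
        if (identical(a, assign_prev) ||
            (is.finite(gev_prev) && abs(g - gev_prev) <=
               tol * max(gev_prev, .Machine$double.eps))) {
          gev_prev <- g
          break
        }
        assign_prev <- a
        gev_prev <- g
      }
      if (is.null(best) || gev_prev > best$gev) {
        best <- list(protos = protos, gev = gev_prev, iterations = iters)
      }
    }
  })
  rownames(best$protos) <- as.character(seq_len(k))
  structure(list(maps = best$protos, labels = as.character(seq_len(k)),
                 gev = best$gev, k = k,
                 channels = colnames(maps) %||% colnames(best$protos),
                 n_restarts = n_restarts, seed = seed,
                 iterations = best$iterations),
            class = "microstate_model")
}

#' Scan k = 2..10 and report GEV per k
#'
#' Runs [modified_kmeans()] for each candidate number of classes and reports
#' the GEV curve. No automatic selection is performed; four classes is the
#' conventional choice.
#'
#' @inheritParams modified_kmeans
#' @param ks Candidate numbers of classes.
#' @return Data frame with columns `k` and `gev`.
#' @export
kmeans_scan <- function(maps, ks = 2:10, n_restarts = 10, seed = 1) {
  data.frame(k = ks, gev = vapply(ks, function(k) {
    modified_kmeans(maps, k, n_restarts = n_restarts,
                    seed = child_seed(seed, k))$gev
  }, 0))
}

#' Align a 4-class model to the canonical A-D templates
#'
#' Finds the one-to-one assignment of fitted maps to the built-in canonical
#' template topographies (see [canonical_templates()]) maximizing the total
#' absolute spatial correlation, by exhaustive search over the 24
#' permutations (optimal, not greedy; ties broken deterministically by
#' enumeration order). Models with k != 4 keep index labels, with a warning.
#'
#' @param model A `microstate_model`.
#' @param templates Template matrix with rownames (default: canonical A-D on
#'   the model's channels).
#' @return The model with `maps` reordered to A-D and `labels` set; the
#'   achieved total correlation is stored as `alignment_corr`.
#' @export
align_to_canonical <- function(model, templates = NULL) {
  stopifnot(inherits(model, "microstate_model"))
  if (is.null(templates)) templates <- canonical_templates(model$channels)
  if (model$k != nrow(templates)) {
    warnf("k = %d does not match %d templates; labels left as indices",
          model$k, nrow(templates))
    return(model)
  }
  cmat <- abs(spatial_corr(t(model$maps), templates))  # fitted x template
  perms <- permutations_of(model$k)
  tot <- vapply(seq_len(nrow(perms)), function(i) {
    sum(cmat[cbind(perms[i, ], seq_len(model$k))])
  }, 0)
  p <- perms[which.max(tot), ]   # p[j] = fitted map assigned to template j
  model$maps <- model$maps[p, , drop = FALSE]
  model$labels <- rownames(templates)
  rownames(model$maps) <- model$labels
  model$alignment_corr <- max(tot)
  model$alignment_perm <- p
  model
}

# All permutations of 1..n (n small), rows in lexicographic order.
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (i in seq_len(nrow(sub))) {
      out[r, ] <- c(first, rest[sub[i, ]])
      r <- r + 1L
    }
  }
  out
}

#' Winner-takes-all backfit of microstate maps onto a recording
#'
#' Labels every sample with the map of highest absolute spatial correlation
#' to the instantaneous topography. No temporal smoothing or minimum-duration
#' constraint is applied.
#'
#' @param model A `microstate_model` (aligned or not).
#' @param rec Average-referenced [eeg_recording()] on the model's montage.
#' @return A `microstate_sequence`: `states` (integer per sample), `labels`
#'   (state names), `corr` (winning absolute correlation per sample),
#'   `fs_hz`, `annotations`.
#' @export
backfit <- function(model, rec) {
  stopifnot(inherits(model, "microstate_model"))
  mism <- c(setdiff(model$channels, rec$channels),
            setdiff(rec$channels, model$channels))
  if (length(mism) > 0 ||
      !identical(as.character(model$channels), as.character(rec$channels))) {
    stopf("montage mismatch between model and recording: %s",
          paste(unique(mism), collapse = ", "))
  }
  corr <- spatial_corr(rec$data, model$maps)
  states <- max.col(abs(corr), ties.method = "first")
  structure(list(states = states,
                 labels = model$labels,
                 corr = abs(corr[cbind(seq_along(states), states)]),
                 fs_hz = rec$fs_hz,
                 annotations = rec$annotations),
            class = "microstate_sequence")
}

#' Global explained variance of a model on a recording
#'
#' `GEV = sum_t (GFP_t * |corr_t|)^2 / sum_t GFP_t^2`, with `corr_t` the
#' winning absolute spatial correlation at sample t.
#'
#' @param model A `microstate_model`.
#' @param rec Average-referenced [eeg_recording()].
#' @return Fraction in 0..1.
#' @export
variance_explained <- function(model, rec) {
  seq <- backfit(model, rec)
  g <- gfp(rec)
  sum((g * seq$corr)^2) / sum(g^2)
}

#' Per-minute microstate duration statistics
#'
#' Run-length-encodes the labelled sequence within each annotated minute and
#' reports the mean duration (ms) and run count per state. Runs touching a
#' minute boundary are included by default (they conserve labelled time);
#' `drop_boundary_runs = TRUE` excludes the first and last run of each
#' minute. A state absent from a minute is recorded as missing, not zero.
#'
#' @param seq A `microstate_sequence` (from [backfit()]) with annotations.
#' @param drop_boundary_runs Exclude runs touching the minute edges.
#' @return Data frame: `minute`, `state`, `mean_ms`, `n_runs`.
#' @export
microstate_durations <- function(seq, drop_boundary_runs = FALSE) {
  stopifnot(inherits(seq, "microstate_sequence"))
  ann <- seq$annotations
  if (is.null(ann)) stopf("sequence has no minute annotations")
  fs <- seq$fs_hz
  k <- length(seq$labels)
  rows <- list()
  for (i in seq_len(nrow(ann))) {
    a <- round(ann$start_s[i] * fs) + 1L
    b <- round(ann$end_s[i] * fs)
    r <- rle(seq$states[a:b])
    keep <- rep(TRUE, length(r$lengths))
    if (drop_boundary_runs && length(keep) > 1) {
      keep[c(1, length(keep))] <- FALSE
    }
    for (s in seq_len(k)) {
      sel <- keep & r$values == s
      rows[[length(rows) + 1]] <- data.frame(
        minute = ann$label[i], state = seq$labels[s],
        mean_ms = if (any(sel)) mean(r$lengths[sel]) * 1000 / fs
                  else NA_real_,
        n_runs = sum(sel), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Microstate duration response relative to baseline
#'
#' Subtracts each state's mean duration in the baseline minute from its mean
#' duration in every other minute.
#'
#' @param dstats Output of [microstate_durations()].
#' @param baseline_minute Label of the baseline minute (default `"B"`).
#' @return Data frame: `minute`, `state`, `response_ms` (duration minus
#'   baseline), for all non-baseline minutes.
#' @export
duration_response <- function(dstats, baseline_minute = "B") {
  base <- dstats[dstats$minute == baseline_minute, ]
  if (nrow(base) == 0) stopf("baseline minute '%s' missing", baseline_minute)
  rest <- dstats[dstats$minute != baseline_minute, ]
  base_ms <- stats::setNames(base$mean_ms, base$state)
  rest$response_ms <- rest$mean_ms - base_ms[rest$state]
  rest[, c("minute", "state", "response_ms")]
}

#' Prepare a recording for microstate analysis
#'
#' Drops the earlobe channels, converts to average reference, band-pass
#' filters 1-30 Hz and downsamples to 125 Hz — the conditioning the
#' microstate stages operate on.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Analysis rate (Hz).
#' @param band Band-pass edges (Hz).
#' @param drop_channels Channels removed before average referencing.
#' @return A conditioned [eeg_recording()].
#' @export
prepare_microstate_data <- function(rec, target_fs = 125, band = c(1, 30),
                                    drop_channels = c("A1", "A2")) {
  keep <- !(rec$channels %in% drop_channels)
  rec <- eeg_recording(rec$data[keep, , drop = FALSE], rec$fs_hz,
                       rec$channels[keep], rec$annotations)
  rec <- rereference(rec, "average")
  bandpass_downsample(rec, band[1], band[2], target_fs = target_fs)
}

#' Cohort-level microstate analysis
#'
#' Concatenates the strongest GFP-peak maps from every subject and analyzed
#' minute, fits one polarity-invariant k-means model for the whole cohort,
#' aligns it to the canonical A-D templates (k = 4), backfits it onto each
#' subject, and assembles per-subject duration and duration-response tables.
#'
#' @param recordings Named list of [eeg_recording()] objects (raw; each is
#'   conditioned with [prepare_microstate_data()]).
#' @param groups Optional named vector subject -> group label.
#' @param k Number of classes (canonical alignment applies when k = 4).
#' @param n_peaks Peak maps per subject-minute.
#' @param n_restarts,seed Passed to [modified_kmeans()].
#' @param exclude_minutes Minutes dropped from the EEG analysis.
#' @param baseline_minute Baseline label for the duration response.
#' @return List: `model`, `sequences`, `durations` (subject, group, minute,
#'   state, mean_ms, n_runs), `responses` (with `response_ms`).
#' @export
fit_cohort_microstates <- function(recordings, groups = NULL, k = 4,
                                   n_peaks = 100, n_restarts = 50, seed = 1,
                                   exclude_minutes = character(0),
                                   baseline_minute = "B") {
  prepped <- lapply(recordings, prepare_microstate_data)
  all_maps <- NULL
  all_w <- numeric(0)
  for (nm in names(prepped)) {
    rec <- prepped[[nm]]
    minutes <- setdiff(rec$annotations$label, exclude_minutes)
    for (m in minutes) {
      rng <- annotation_samples(rec, m)
      sub <- eeg_recording(rec$data[, rng["start"]:rng["end"], drop = FALSE],
                           rec$fs_hz, rec$channels)
      pk <- gfp_peaks(gfp(sub))
      maps <- sample_peak_maps(sub, pk, n = n_peaks)
      all_maps <- rbind(all_maps, maps)
      all_w <- c(all_w, attr(maps, "gfp"))
    }
  }
  attr(all_maps, "gfp") <- all_w
  model <- modified_kmeans(all_maps, k, n_restarts = n_restarts, seed = seed)
  if (k == 4) model <- align_to_canonical(model)

  sequences <- lapply(prepped, function(rec) backfit(model, rec))
  dur <- do.call(rbind, lapply(names(sequences), function(nm) {
    d <- microstate_durations(sequences[[nm]])
    d <- d[!d$minute %in% exclude_minutes, ]
    d$subject <- nm
    d$group <- if (!is.null(groups)) groups[[nm]] else NA_character_
    d
  }))
  resp <- do.call(rbind, lapply(names(sequences), function(nm) {
    d <- microstate_durations(sequences[[nm]])
    d <- d[!d$minute %in% setdiff(exclude_minutes, baseline_minute), ]
    r <- duration_response(d, baseline_minute)
    r$subject <- nm
    r$group <- if (!is.null(groups)) groups[[nm]] else NA_character_
    r
  }))
  list(model = model, sequences = sequences, durations = dur,
       responses = resp)
}
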