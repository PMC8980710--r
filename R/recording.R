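#' Construct an EEG recording object
#'
#' Container for a continuous multi-channel recording in microvolts with
#' minute annotations. Annotations are half-open intervals `[start_s, end_s)`
#' labelling the session minutes (resting baseline `B`, induction minutes
#' `LKM1`..`LKM11`, post baseline `P`).
#'
#' @param data Channels x time numeric matrix (microvolts).
#' @param fs_hz Sampling rate in Hz.
#' @param channels Character vector of channel labels, one per row of `data`.
#' @param annotations Data frame with columns `label`, `start_s`, `end_s`
#'   (half-open, seconds), or `NULL`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs_hz, channels, annotations = NULL) {
  data <- as.matrix(data)
  if (nrow(data) != length(channels)) {
    stopf("data has %d rows but %d channel labels given",
          nrow(data), length(channels))
  }
  if (anyDuplicated(channels)) stopf("duplicate channel labels")
  if (!is.null(annotations)) {
    stopifnot(all(c("label", "start_s", "end_s") %in% names(annotations)))
    if (anyDuplicated(annotations$label)) stopf("duplicate annotation labels")
    n_s <- ncol(data) / fs_hz
    if (any(annotations$start_s < 0) || any(annotations$end_s > n_s + 1e-9)) {
      stopf("annotation interval outside recording (length %.3f s)", n_s)
    }
  }
  structure(
    list(data = data, fs_hz = fs_hz, channels = as.character(channels),
         annotations = annotations),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz))
  if (!is.null(x$annotations)) {
    cat("  minutes:", paste(x$annotations$label, collapse = " "), "\n")
  }
  invisible(x)
}

# Sample index range (1-based, half-open upper bound exclusive at end+1) for
# an annotated minute.
annotation_samples <- function(rec, label) {
  ann <- rec$annotations
  if (is.null(ann) || !label %in% ann$label) {
    stopf("minute '%s' is not annotated", label)
  }
  row <- ann[ann$label == label, ]
  start <- round(row$start_s * rec$fs_hz) + 1L
  end <- round(row$end_s * rec$fs_hz)  # inclusive last sample of [start, end)
  c(start = start, end = end)
}

# Standard session annotation table: B, LKM1..LKMn, optionally P, each 60 s.
session_annotations <- function(n_lkm = 11, post = FALSE, minute_s = 60) {
  labels <- c("B", if (n_lkm > 0) paste0("LKM", seq_len(n_lkm)), if (post) "P")
  data.frame(
    label = labels,
    start_s = (seq_along(labels) - 1) * minute_s,
    end_s = seq_along(labels) * minute_s,
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# EDF input/output.
#
# Minimal continuous EDF (16-bit) writer and reader implemented directly over
# readBin/writeBin. One data record per second; per-channel physical scaling
# from the data range, so round-trip error is bounded by the 16-bit
# quantization step (range / 65535). Annotations and generator ground truth
# travel in a JSON sidecar, not inside the EDF.
# ---------------------------------------------------------------------------

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' Writes continuous 16-bit EDF with one data record per second. The
#' recording length must be a whole number of seconds.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs_hz
  if (abs(fs - round(fs)) > 1e-9) stopf("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  n <- ncol(rec$data)
  if (n %% fs != 0) stopf("recording length must be a whole number of seconds")
  n_rec <- n %/% fs
  ns <- nrow(rec$data)

  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1  # avoid zero scale for flat channels
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate 01-JAN-2000 X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + 256 * ns, 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (lb in rec$channels) wr(lb, 16)
  for (i in seq_len(ns)) wr("", 80)          # transducer
  for (i in seq_len(ns)) wr("uV", 8)         # physical dimension
  for (i in seq_len(ns)) wr(sprintf("%.8g", phys_min[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", phys_max[i]), 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)          # prefiltering
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((rec$data[i, cols] - phys_min[i]) / scale[i] + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @param annotations Optional annotation data frame to attach.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, annotations = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) stopf("mixed sampling rates not supported")
  fs <- spr[1] / rec_dur

  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
      cols <- ((r - 1) * spr[i] + 1):(r * spr[i])
      data[i, cols] <- (dig - dig_min[i]) * scale[i] + phys_min[i]
    }
  }
  eeg_recording(data, fs, labels, annotations)
}

#' Write a recording plus JSON sidecar (annotations and ground truth)
#'
#' @param rec An [eeg_recording()]; its annotations and any `ground_truth`
#'   attribute are stored in `<path>.json`.
#' @param path EDF file path (sidecar path is derived from it).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  write_edf(rec, path)
  side <- list(fs_hz = rec$fs_hz, annotations = rec$annotations)
  gt <- attr(rec, "ground_truth")
  if (!is.null(gt)) {
    # named atomic vectors keep their names as JSON object keys
    side$ground_truth <- lapply(gt, function(x) {
      if (is.atomic(x) && !is.null(names(x)) && !is.matrix(x)) as.list(x)
      else x
    })
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#' @param path EDF file path.
#' @return An [eeg_recording()] with annotations (and ground truth attribute)
#'   restored from the sidecar.
#' @export
read_recording <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ann <- side$annotations
  rec <- read_edf(path, annotations = ann)
  if (!is.null(side$ground_truth)) {
    attr(rec, "ground_truth") <- side$ground_truth
  }
  rec
}
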