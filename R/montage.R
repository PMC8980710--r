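#' Electrode clusters used for hemispheric alpha asymmetry
#'
#' Anterior and posterior left/right electrode clusters over which alpha-band
#' power densities are averaged before forming ln(right) - ln(left) asymmetry
#' scores. These are fixed sets of 10-10 electrode names.
#'
#' @return A named list with character vectors `anterior_left`,
#'   `anterior_right`, `posterior_left`, `posterior_right`.
#' @export
#' @examples
#' asymmetry_clusters()$anterior_left
asymmetry_clusters <- function() {
  list(
    anterior_left  = c("F3", "F5", "F7", "FC5", "FT7", "T7"),
    anterior_right = c("F4", "F6", "F8", "FC6", "FT8", "T8"),
    posterior_left  = c("CP5", "P3", "P5", "P7"),
    posterior_right = c("CP6", "P4", "P6", "P8")
  )
}

# Left/right homologous pairs inside the asymmetry clusters, used by the
# generator to inject an exact ln(R/L) power offset.
cluster_pairs <- function() {
  list(
    anterior = cbind(
      left  = c("F3", "F5", "F7", "FC5", "FT7", "T7"),
      right = c("F4", "F6", "F8", "FC6", "FT8", "T8")
    ),
    posterior = cbind(
      left  = c("CP5", "P3", "P5", "P7"),
      right = c("CP6", "P4", "P6", "P8")
    )
  )
}

#' Default 10-10 montage for synthetic recordings
#'
#' Thirty scalp electrodes covering the standard 10-10 positions required by
#' the asymmetry clusters, plus the two earlobe electrodes `A1`/`A2` used for
#' linked-mastoid referencing.
#'
#' @return Character vector of channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F7", "F5", "F3", "Fz", "F4", "F6", "F8",
    "FT7", "FC5", "FC6", "FT8", "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP6", "P7", "P5", "P3", "Pz", "P4", "P6", "P8",
    "O1", "Oz", "O2", "A1", "A2")
}

# Approximate 2-D head positions (x: left -, right +; y: posterior -,
# anterior +) parsed from 10-10 labels. Only used to build the synthetic
# canonical topographies; not a geodesic model.
electrode_positions <- function(labels) {
  row_y <- c(Fp = 0.90, AF = 0.75, F = 0.55, FT = 0.30, FC = 0.30,
             T = 0.00, C = 0.00, TP = -0.30, CP = -0.30,
             P = -0.55, PO = -0.75, O = -0.90, A = 0.00)
  idx_x <- c(z = 0, "1" = 0.20, "2" = 0.20, "3" = 0.42, "4" = 0.42,
             "5" = 0.64, "6" = 0.64, "7" = 0.84, "8" = 0.84,
             "9" = 1.05, "10" = 1.05)
  pos <- t(vapply(labels, function(lb) {
    m <- regmatches(lb, regexec("^([A-Za-z]+)(z|[0-9]+)$", lb))[[1]]
    if (length(m) != 3) stopf("cannot parse electrode label '%s'", lb)
    row <- m[2]; idx <- m[3]
    if (!row %in% names(row_y)) stopf("unknown electrode row in '%s'", lb)
    y <- row_y[[row]]
    x <- idx_x[[idx]]
    if (idx != "z" && as.integer(idx) %% 2 == 1) x <- -x
    if (row == "A") x <- sign(x) * 1.1  # earlobes sit lateral of the scalp
    c(x = x, y = y)
  }, numeric(2)))
  rownames(pos) <- labels
  pos
}

#' Canonical microstate template topographies (synthetic)
#'
#' Builds idealized template maps for the four classic microstate classes A-D
#' on a given montage: A and B are the two mirror-image diagonal gradients
#' (left-posterior to right-anterior and its mirror), C is a symmetric
#' anterior-posterior pattern with an occipital focus, and D a fronto-central
#' focal pattern. The templates are **synthetic stand-ins** constructed from
#' idealized electrode geometry (no empirical grand-average maps ship with the
#' package); they serve as the fixed reference for canonical labeling and as
#' default planted maps for the synthetic cohort generator.
#'
#' Maps are average-referenced across channels and scaled to unit Euclidean
#' norm; earlobe channels (`A1`, `A2`) are set to zero before referencing.
#'
#' @param channels Character vector of channel labels
#'   (default [default_montage()]).
#' @return A 4 x n_channels matrix with rownames `A`-`D`, unit-norm rows.
#' @export
#' @examples
#' tm <- canonical_templates()
#' round(rowSums(tm^2), 10)
canonical_templates <- function(channels = default_montage()) {
  pos <- electrode_positions(channels)
  scalp <- !(channels %in% c("A1", "A2"))
  x <- pos[, "x"]; y <- pos[, "y"]
  blob <- function(cx, cy, w) exp(-((x - cx)^2 + (y - cy)^2) / w)
  maps <- rbind(
    A = x + 0.7 * y,
    B = 0.7 * y - x,
    C = blob(0, -0.85, 0.35),
    D = blob(0, 0.15, 0.28)
  )
  maps[, !scalp] <- 0
  maps <- t(apply(maps, 1, function(m) {
    m[scalp] <- m[scalp] - mean(m[scalp])
    m / sqrt(sum(m^2))
  }))
  # symmetric (Loewdin) orthogonalization: the orthonormal set closest to the
  # idealized shapes, so the four classes are mutually uncorrelated
  e <- eigen(maps %*% t(maps), symmetric = TRUE)
  w <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  maps <- w %*% maps
  maps <- maps / sqrt(rowSums(maps^2))
  rownames(maps) <- c("A", "B", "C", "D")
  colnames(maps) <- channels
  maps
}
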