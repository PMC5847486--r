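# Per-tile matching: in-plane angle from rotational correlation of power
# spectra (layer lines make the amplitude spectrum translation-invariant),
# then normal shift and cc-score from one real-space cross-correlation of
# the back-rotated tile with the reference.

# Annular mask used on power spectra: exclude a small low-frequency disc
# (radius 2 Fourier px, dominated by the real-space mask envelope) and the
# corners beyond Nyquist.
ps_annulus <- function(n, r_min = 2) {
  ctr <- fft_center(n)
  r <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  r > r_min & r <= n / 2
}

# log-scale power-spectrum values to compress dynamic range
ps_scale <- function(ps) log1p(ps)

# Rotated-reference correlation stack: one centered, unit-norm row per angle.
# Reused across all tiles of a micrograph.
rotation_stack <- function(ref_ps, angular_step_deg = 1) {
  n <- nrow(ref_ps)
  angles <- seq(0, 180 - angular_step_deg, by = angular_step_deg)
  mask <- ps_annulus(n)
  sc <- ps_scale(ref_ps)
  stack <- matrix(0, length(angles), sum(mask))
  for (i in seq_along(angles)) {
    rot <- if (angles[i] == 0) sc else rotate_image(sc, angles[i])
    v <- rot[mask]
    v <- v - mean(v)
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    stack[i, ] <- v
  }
  list(angles = angles, stack = stack, mask = mask)
}

#' In-plane angle by rotational power-spectrum correlation
#'
#' Finds the rotation of the reference power spectrum that best matches the
#' tile power spectrum (normalized correlation over an annulus excluding the
#' lowest frequencies and the corners beyond Nyquist; intensities are
#' log-scaled). Because power spectra of real images have Friedel symmetry,
#' angles are searched over `[0, 180)` only. Ties are broken toward the
#' smallest angle.
#'
#' @param tile_ps,ref_ps centered square power spectra of equal size.
#' @param angular_step_deg angular sampling in degrees (default 1).
#' @return best angle `theta_deg` in `[0, 180)`.
#' @export
rotational_correlation <- function(tile_ps, ref_ps, angular_step_deg = 1) {
  stopifnot(all(dim(tile_ps) == dim(ref_ps)), nrow(tile_ps) == ncol(tile_ps))
  if (all(tile_ps == 0) || all(ref_ps == 0))
    stop("undefined angle: all-zero power spectrum")
  rs <- rotation_stack(ref_ps, angular_step_deg)
  rotational_correlation_stack(tile_ps, rs)$theta
}

# stack-based variant used in the per-micrograph loop
rotational_correlation_stack <- function(tile_ps, rs) {
  v <- ps_scale(tile_ps)[rs$mask]
  v <- v - mean(v)
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(list(theta = 0, score = 0))
  scores <- as.numeric(rs$stack %*% (v / nv))
  best <- which.max(scores)  # which.max returns the first (smallest angle) tie
  list(theta = rs$angles[best], score = scores[best])
}

#' Normal shift and cc-score by real-space cross-correlation
#'
#' Rotates the tile by `-theta` so its helix axis is vertical like the
#' reference, computes the normalized cross-correlation via FFT, and locates
#' the peak. Only the horizontal component of the peak shift -- the offset of
#' the helix axis from the tile center, normal to the axis -- is kept; the
#' axial component carries no information for a (locally) straight helix.
#' Peaks are found at integer precision; equal maxima resolve to the smallest
#' `|delta|`.
#'
#' @param tile masked tile (already mean-subtracted).
#' @param theta_deg in-plane angle from [rotational_correlation()].
#' @param ref_image prepared reference image (same size as the tile).
#' @return list with `delta_px` (signed normal offset) and `cc_score`
#'   (normalized correlation peak in `[-1, 1]`).
#' @export
translational_match <- function(tile, theta_deg, ref_image) {
  stopifnot(all(dim(tile) == dim(ref_image)))
  n <- nrow(tile)
  tile <- tile - mean(tile)  # before rotation: zero fill stays neutral
  trot <- if (theta_deg == 0) tile else rotate_image(tile, -theta_deg)
  trot <- trot - mean(trot)
  rimg <- ref_image - mean(ref_image)
  nt <- sqrt(sum(trot^2)); nr <- sqrt(sum(rimg^2))
  if (nt == 0 || nr == 0) return(list(delta_px = 0, cc_score = 0))
  cc <- Re(stats::fft(stats::fft(trot) * Conj(stats::fft(rimg)),
                      inverse = TRUE)) / (n * n * nt * nr)
  # cc[k] = sum_j tile[j] ref[j - k]: the peak index is the shift of the
  # reference (axis position relative to tile center)
  sx <- freq_axis(n) * n  # signed shifts 0, 1, ..., -1 matching cc layout
  dx <- matrix(sx, n, n, byrow = TRUE)
  ok <- abs(dx) <= n / 2
  peak <- max(cc[ok])
  cand <- which(cc >= peak - 1e-12 & ok, arr.ind = TRUE)
  dxs <- sx[cand[, 2]]
  delta <- dxs[which.min(abs(dxs))]
  list(delta_px = delta, cc_score = max(-1, min(1, peak)))
}

#' Match every tile of a micrograph against the reference
#'
#' Runs the separated angle/shift search for all tiles of the grid. Tiles are
#' independent of each other: the result does not depend on processing order.
#' Degenerate tiles (zero variance) are reported with `cc_score` 0.
#'
#' @param m preprocessed (binned, filtered) [micrograph()].
#' @param grid a `tile_grid` for `m`.
#' @param ref prepared reference from [prepare_reference()].
#' @param params [tracing_params()].
#' @return data.frame of class `tile_matches` with one row per tile:
#'   `tile_index`, `theta_deg`, `delta_px`, `cc_score`.
#' @export
match_all_tiles <- function(m, grid, ref, params) {
  rs <- rotation_stack(ref$power_spectrum, params$angular_step_deg)
  nt <- nrow(grid$origins)
  theta <- numeric(nt); delta <- numeric(nt); cc <- numeric(nt)
  # cache back-rotation gathers per discrete angle
  rmap_cache <- new.env(parent = emptyenv())
  ts <- grid$tile_size_px
  rimg <- ref$image - mean(ref$image)
  nrm_ref <- sqrt(sum(rimg^2))
  fref <- Conj(stats::fft(rimg))
  sx <- freq_axis(ts) * ts
  dxmat_ok <- abs(matrix(sx, ts, ts, byrow = TRUE)) <= ts / 2
  for (i in seq_len(nt)) {
    tile <- extract_tile(m, grid$origins[i, ], grid)
    if (all(tile == 0) || stats::sd(as.numeric(tile)) == 0) {
      theta[i] <- 0; delta[i] <- 0; cc[i] <- 0
      next
    }
    tile <- tile - mean(tile)
    th <- rotational_correlation_stack(power_spectrum(tile), rs)$theta
    key <- format(th)
    rmap <- rmap_cache[[key]]
    if (is.null(rmap) && th != 0) {
      rmap <- rotation_map(ts, -th)
      rmap_cache[[key]] <- rmap
    }
    trot <- if (th == 0) tile else apply_rotation_map(tile, rmap)
    trot <- trot - mean(trot)
    nt2 <- sqrt(sum(trot^2))
    if (nt2 == 0 || nrm_ref == 0) { theta[i] <- th; next }
    ccm <- Re(stats::fft(stats::fft(trot) * fref, inverse = TRUE)) /
      (ts * ts * nt2 * nrm_ref)
    peak <- max(ccm[dxmat_ok])
    cand <- which(ccm >= peak - 1e-12 & dxmat_ok, arr.ind = TRUE)
    dxs <- sx[cand[, 2]]
    theta[i] <- th
    delta[i] <- dxs[which.min(abs(dxs))]
    cc[i] <- max(-1, min(1, peak))
  }
  structure(data.frame(tile_index = seq_len(nt), theta_deg = theta,
                       delta_px = delta, cc_score = cc),
            class = c("tile_matches", "data.frame"))
}
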