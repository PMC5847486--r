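# Synthetic micrographs with known ground truth: filaments follow simulated
# worm-like-chain paths, carry a repeating axial density (which produces the
# layer lines the rotational search relies on), and sit in additive Gaussian
# white noise at a controlled signal-to-noise ratio. These scenes emulate
# the geometry and contrast statistics of cryo-micrographs of helical
# specimens, not their full image-formation physics (no CTF, no structured
# ice or carbon background).

# soft-edged cross-section profile of a filament of the given full width
ribbon_profile <- function(d, width) {
  ifelse(abs(d) <= width / 2, cos(pi * d / width)^2, 0)
}

# axial intensity modulation with period `repeat_A` (modulation depth 0.5)
axial_modulation <- function(t, repeat_A) {
  (1 + 0.5 * cos(2 * pi * t / repeat_A)) / 1.5
}

# render one path (Angstrom polyline) into the signal matrix by stamping
# cross-sections at fine arc steps; stamps combine by maximum so overlapping
# stamps of the same filament do not double-count
render_path <- function(signal, path_A, width_A, repeat_A, pixel_size_A) {
  n <- nrow(signal)
  seg <- sqrt(rowSums(diff(path_A)^2))
  arc0 <- c(0, cumsum(seg))
  step <- pixel_size_A / 2
  r_px <- ceiling(width_A / 2 / pixel_size_A) + 1L
  for (i in seq_along(seg)) {
    if (seg[i] == 0) next
    ts <- seq(0, seg[i], by = step)
    dir <- (path_A[i + 1, ] - path_A[i, ]) / seg[i]
    for (t in ts) {
      pos <- path_A[i, ] + t * dir
      amp <- axial_modulation(arc0[i] + t, repeat_A)
      cx <- pos[1] / pixel_size_A; cy <- pos[2] / pixel_size_A
      xs <- max(0, floor(cx - r_px)):min(n - 1, ceiling(cx + r_px))
      ys <- max(0, floor(cy - r_px)):min(n - 1, ceiling(cy + r_px))
      if (!length(xs) || !length(ys)) next
      d2 <- outer((ys - cy)^2, (xs - cx)^2, "+") * pixel_size_A^2
      stamp <- amp * ribbon_profile(sqrt(d2), width_A)
      blk <- signal[ys + 1, xs + 1, drop = FALSE]
      signal[ys + 1, xs + 1] <- pmax(blk, stamp)
    }
  }
  signal
}

#' Generate a synthetic micrograph scene with ground truth
#'
#' Filament center lines are simulated as planar worm-like chains at the
#' requested persistence length, placed with uniformly random start points
#' and directions (re-drawn until the whole path fits inside the frame).
#' The filament density is a soft-edged ribbon of the given width with a
#' sinusoidal axial modulation, and Gaussian white noise is added so that
#' `var(signal) / var(noise)` equals `snr`.
#'
#' @param n_filaments number of filaments.
#' @param persistence_p_A persistence length of the filament paths (A).
#' @param helix_width_A filament width (A).
#' @param axial_repeat_A period of the axial density modulation (A).
#' @param snr signal variance / noise variance; `Inf` for no noise.
#' @param image_A image edge length (A).
#' @param pixel_size_A pixel size (A/px).
#' @param seed integer seed; the scene is reproducible bit-exactly.
#' @param length_range_A range of filament contour lengths to draw from.
#' @return object of class `synthetic_scene`: list with `micrograph`,
#'   `truth_traces` (list of Angstrom coordinate matrices), `signal` and the
#'   generating parameters.
#' @export
generate_synthetic_scene <- function(n_filaments = 10,
                                     persistence_p_A = 33.9e4,
                                     helix_width_A = 100,
                                     axial_repeat_A = 50, snr = 0.1,
                                     image_A = 4000, pixel_size_A = 10,
                                     seed = 1L,
                                     length_range_A = c(800, 1600)) {
  stopifnot(n_filaments >= 0, helix_width_A > 0, axial_repeat_A > 0,
            image_A > 0, pixel_size_A > 0, snr > 0)
  buffer <- helix_width_A
  if (max(length_range_A) + 2 * buffer > sqrt(2) * image_A)
    stop("filaments cannot fit in the image")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  seg_A <- 20
  truth <- vector("list", n_filaments)
  for (i in seq_len(n_filaments)) {
    contour <- stats::runif(1, length_range_A[1], length_range_A[2])
    for (try in seq_len(500)) {
      chain_seed <- sample.int(.Machine$integer.max, 1)
      ch <- simulate_wlc(1, contour, seg_A, persistence_p_A,
                         seed = chain_seed)$chains[[1]]
      start <- stats::runif(2, buffer, image_A - buffer)
      path <- sweep(ch, 2, c(start[1] - ch[1, 1], start[2] - ch[1, 2]), "+")
      if (all(path >= buffer) && all(path <= image_A - buffer)) break
      path <- NULL
    }
    if (is.null(path))
      stop("could not place filament ", i, " inside the image")
    colnames(path) <- c("x", "y")
    truth[[i]] <- path
  }
  n_px <- round(image_A / pixel_size_A)
  signal <- matrix(0, n_px, n_px)
  for (path in truth)
    signal <- render_path(signal, path, helix_width_A, axial_repeat_A,
                          pixel_size_A)
  if (is.finite(snr)) {
    sig_sd <- stats::sd(as.numeric(signal))
    if (sig_sd == 0) sig_sd <- 1  # empty scene: unit-variance noise
    noise_sd <- sig_sd / sqrt(snr)
    noise <- matrix(stats::rnorm(n_px * n_px, 0, noise_sd), n_px, n_px)
  } else {
    noise_sd <- 0
    noise <- matrix(0, n_px, n_px)
  }
  # cryo contrast: protein is dark; tracing normalizes this away, but keep
  # the synthetic image light-on-dark like the reference for clarity
  m <- micrograph(signal + noise, pixel_size_A,
                  source_id = sprintf("synthetic-seed%d", seed))
  structure(list(micrograph = m, truth_traces = truth, signal = signal,
                 noise_sd = noise_sd, helix_width_A = helix_width_A,
                 axial_repeat_A = axial_repeat_A, snr = snr,
                 persistence_p_A = persistence_p_A, seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' Synthetic vertical reference helix
#'
#' Renders a straight vertical filament with the same ribbon profile and
#' axial modulation as [generate_synthetic_scene()], for use as the matching
#' reference on synthetic scenes.
#'
#' @param helix_width_A filament width (A).
#' @param axial_repeat_A axial modulation period (A).
#' @param pixel_size_A pixel size (A/px).
#' @param size_px edge length of the (square) reference image in pixels.
#' @return a [reference_helix()].
#' @export
synthetic_reference <- function(helix_width_A, axial_repeat_A, pixel_size_A,
                                size_px = 64) {
  ctr <- fft_center(size_px)
  x_A <- (seq_len(size_px) - ctr) * pixel_size_A
  y_A <- (seq_len(size_px) - ctr) * pixel_size_A
  cross <- ribbon_profile(x_A, helix_width_A)
  axial <- axial_modulation(y_A, axial_repeat_A)
  reference_helix(outer(axial, cross), pixel_size_A, helix_width_A)
}
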