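#' Tracing parameters
#'
#' Bundles the user-facing tracing parameters. Typical values for helical
#' specimens: tile sizes of 350-500 A, 80 percent tile overlap (giving an
#' effective step of 70-100 A), binning to roughly 5-10 A/px, and a
#' significance level alpha around 1e-3 for thresholding the correlation map.
#'
#' @param tile_size_A tile edge length in Angstrom (350-500 typical).
#' @param overlap_pct tile overlap percentage in `[0, 100)` (80 typical).
#' @param binning_factor positive integer block-binning factor.
#' @param helix_width_A estimated helix width in Angstrom.
#' @param min_helix_len_A minimum accepted trace contour length in Angstrom.
#' @param max_helix_len_A maximum trace length; longer traces are split.
#' @param alpha significance level in (0, 1] for thresholding against the
#'   exponential null distribution of correlation-map values.
#' @param prune_n_sigma robust-SD multiple for persistence-length pruning.
#' @param segment_spacing_A spacing of exported segment coordinates.
#' @param angular_step_deg angular sampling of the rotational search.
#' @param seed integer seed for any stochastic step.
#' @return object of class `tracing_params`.
#' @export
tracing_params <- function(tile_size_A = 500, overlap_pct = 80,
                           binning_factor = 4, helix_width_A = 100,
                           min_helix_len_A = 500, max_helix_len_A = 1500,
                           alpha = 0.001, prune_n_sigma = 2,
                           segment_spacing_A = 70, angular_step_deg = 1,
                           seed = 1L) {
  stopifnot(tile_size_A > 0, overlap_pct >= 0, overlap_pct < 100,
            binning_factor >= 1, binning_factor == round(binning_factor),
            helix_width_A > 0, min_helix_len_A < max_helix_len_A,
            alpha > 0, alpha <= 1, segment_spacing_A > 0)
  structure(list(tile_size_A = tile_size_A, overlap_pct = overlap_pct,
                 binning_factor = as.integer(binning_factor),
                 helix_width_A = helix_width_A,
                 min_helix_len_A = min_helix_len_A,
                 max_helix_len_A = max_helix_len_A, alpha = alpha,
                 prune_n_sigma = prune_n_sigma,
                 segment_spacing_A = segment_spacing_A,
                 angular_step_deg = angular_step_deg,
                 seed = as.integer(seed)),
            class = "tracing_params")
}

normalize_pixels <- function(px) {
  s <- stats::sd(as.numeric(px))
  if (!is.finite(s) || s == 0) s <- 1  # constant image: define SD = 1
  (px - mean(px)) / s
}

#' Normalize and bin a micrograph
#'
#' Block-averages the image by an integer factor (remainder rows/columns are
#' dropped), then normalizes to zero mean and unit standard deviation. The
#' pixel size grows by the binning factor. Binning reduces computational cost
#' and the fine-grained shot noise; helix tracing needs only low-resolution
#' contrast.
#'
#' @param m a [micrograph()].
#' @param binning_factor positive integer; must not exceed either dimension.
#' @return binned, normalized [micrograph()].
#' @export
normalize_and_bin <- function(m, binning_factor = 1) {
  f <- as.integer(binning_factor)
  if (f < 1) stop("binning_factor must be >= 1")
  px <- m$pixels
  if (f > min(dim(px))) stop("binning factor larger than image dimension")
  if (f > 1) {
    nr <- nrow(px) %/% f; nc <- ncol(px) %/% f
    px <- px[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
    # average f x f blocks: fold rows, then columns
    px <- matrix(colMeans(matrix(px, nrow = f)), nrow = nr)        # rows
    px <- t(matrix(colMeans(matrix(t(px), nrow = f)), nrow = nc))  # cols
  }
  micrograph(normalize_pixels(px), m$pixel_size_A * f, m$source_id)
}

#' Gaussian high-pass filter
#'
#' Removes gray-scale ramps by multiplying the Fourier transform with
#' `G(k) = 1 - exp(-k^2 / (2 sigma_f^2))` where `sigma_f` is chosen so that
#' the gain is exactly 1/2 at 4 percent of the Nyquist frequency. The DC
#' component is fully removed and the gain increases monotonically with
#' frequency.
#'
#' @param m a [micrograph()] (normally already normalized).
#' @param half_max_frac fraction of Nyquist at which the gain is 1/2.
#' @return filtered [micrograph()].
#' @export
highpass <- function(m, half_max_frac = 0.04) {
  px <- m$pixels
  k0 <- half_max_frac * 0.5                 # cycles/px; Nyquist = 0.5
  sigma_f <- k0 / sqrt(2 * log(2))          # G(k0) = 1/2
  ky <- freq_axis(nrow(px)); kx <- freq_axis(ncol(px))
  k2 <- outer(ky^2, kx^2, "+")
  G <- 1 - exp(-k2 / (2 * sigma_f^2))
  out <- Re(stats::fft(stats::fft(px) * G, inverse = TRUE)) / length(px)
  micrograph(out, m$pixel_size_A, m$source_id)
}

#' Suppress extreme dark outlier pixels
#'
#' Fits a normal model to the pixel intensities with robust estimates
#' (location = median, scale = 1.4826 x MAD) and replaces pixels whose
#' lower-tail p-value falls below `p_cut` with the median. This removes very
#' dark features such as gold beads or ice crystals that would otherwise
#' dominate the correlation. Only the lower tail is tested by default since
#' the troublesome features are dark.
#'
#' @param m a [micrograph()].
#' @param p_cut lower-tail probability cutoff (default 0.001).
#' @param symmetric also replace the corresponding bright outliers.
#' @return cleaned [micrograph()].
#' @export
suppress_outliers <- function(m, p_cut = 0.001, symmetric = FALSE) {
  px <- m$pixels
  med <- stats::median(px)
  s <- 1.4826 * stats::mad(px, constant = 1)
  if (s == 0) return(m)  # constant image: nothing to test
  z <- (px - med) / s
  bad <- stats::pnorm(z) < p_cut
  if (symmetric) bad <- bad | stats::pnorm(z, lower.tail = FALSE) < p_cut
  px[bad] <- med
  micrograph(px, m$pixel_size_A, m$source_id)
}

#' Build the overlapping tile grid
#'
#' Windows the image into overlapping square tiles. The step between tiles is
#' `tile_size_px * (1 - overlap/100)`; with 80 percent overlap and 350-500 A
#' tiles this gives an effective step of 70-100 A, which sets how finely the
#' correlation map is sampled. The last tile of each row/column is clamped so
#' it ends on the image edge, keeping filaments near edges traceable. Each
#' tile is later multiplied by a circular Gaussian mask with a standard
#' deviation of 1.41 times the step to improve separation of closely packed
#' helices.
#'
#' @param shape integer vector (rows, cols) of the working image.
#' @param params [tracing_params()].
#' @param pixel_size_A working (binned) pixel size.
#' @return object of class `tile_grid` with fields `tile_size_px`, `step_px`,
#'   `origins` (matrix of 0-based (row, col) top-left corners, row-major) and
#'   `mask_sigma_px`.
#' @export
make_tile_grid <- function(shape, params, pixel_size_A) {
  ts <- round(params$tile_size_A / pixel_size_A)
  if (ts > min(shape)) stop("tile size exceeds image dimensions")
  step <- max(1L, as.integer(round(ts * (1 - params$overlap_pct / 100))))
  axis_origins <- function(n) {
    o <- seq(0L, max(0L, n - ts), by = step)
    if (o[length(o)] != n - ts) o <- c(o, n - ts)  # clamp last tile to edge
    as.integer(o)
  }
  oy <- axis_origins(shape[1]); ox <- axis_origins(shape[2])
  origins <- cbind(row = rep(oy, each = length(ox)),
                   col = rep(ox, times = length(oy)))
  structure(list(tile_size_px = as.integer(ts), step_px = step,
                 origins = origins, mask_sigma_px = 1.41 * step),
            class = "tile_grid")
}

#' Extract one masked tile
#'
#' Cuts the tile at the given 0-based origin, subtracts its mean and applies
#' the grid's circular Gaussian real-space mask centered on the tile center.
#'
#' @param m a [micrograph()].
#' @param origin 0-based (row, col) of the tile's top-left corner.
#' @param grid a `tile_grid`.
#' @return `tile_size_px` x `tile_size_px` numeric matrix.
#' @export
extract_tile <- function(m, origin, grid) {
  ts <- grid$tile_size_px
  t0 <- m$pixels[origin[1] + seq_len(ts), origin[2] + seq_len(ts), drop = FALSE]
  (t0 - mean(t0)) * gaussian_mask(ts, grid$mask_sigma_px)
}

#' Construct a reference helix object
#'
#' The reference is an image of a single helix with its axis aligned
#' vertically, typically a class average from a few interactively traced
#' helices (a single traced helix suffices for high-contrast specimens).
#' Contrast-transfer-function correction is unnecessary: tracing relies on
#' low-frequency contrast only.
#'
#' @param pixels numeric matrix, helix axis vertical.
#' @param pixel_size_A pixel size in Angstrom.
#' @param helix_width_A estimated helix width in Angstrom.
#' @return object of class `reference_helix`.
#' @export
reference_helix <- function(pixels, pixel_size_A, helix_width_A) {
  stopifnot(helix_width_A > 0, pixel_size_A > 0)
  structure(list(pixels = as.matrix(pixels), pixel_size_A = pixel_size_A,
                 helix_width_A = helix_width_A),
            class = "reference_helix")
}

#' Prepare the reference for matching
#'
#' Resamples the reference to the working pixel size if needed, pads or crops
#' it centered to the tile size, subtracts the mean, applies the same
#' Gaussian mask as the tiles, and computes its centered power spectrum.
#'
#' @param ref a [reference_helix()].
#' @param grid a `tile_grid`.
#' @param pixel_size_A working (binned) pixel size of the micrograph.
#' @return list with `image` (masked reference tile) and `power_spectrum`
#'   (zero-frequency centered).
#' @export
prepare_reference <- function(ref, grid, pixel_size_A) {
  px <- ref$pixels
  if (abs(ref$pixel_size_A - pixel_size_A) > 1e-6 * pixel_size_A)
    px <- resample_image(px, pixel_size_A / ref$pixel_size_A)
  ts <- grid$tile_size_px
  if (round(ref$helix_width_A / pixel_size_A) > ts)
    stop("reference helix wider than the tile")
  out <- matrix(0, ts, ts)
  # align the centers of the two frames
  rc <- fft_center(nrow(px)); cc <- fft_center(ncol(px)); ct <- fft_center(ts)
  rows <- seq_len(nrow(px)) - rc + ct
  cols <- seq_len(ncol(px)) - cc + ct
  rok <- rows >= 1 & rows <= ts; cok <- cols >= 1 & cols <= ts
  out[rows[rok], cols[cok]] <- px[rok, cok, drop = FALSE]
  out <- (out - mean(out)) * gaussian_mask(ts, grid$mask_sigma_px)
  list(image = out, power_spectrum = power_spectrum(out))
}
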