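# Shared low-level image operations: FFT layout helpers, bilinear rotation,
# Gaussian masks. All functions work on plain numeric matrices (rows = y).

# Index (1-based) of the zero-frequency pixel after fftshift, per dimension.
fft_center <- function(n) floor(n / 2) + 1L

# Move zero frequency to the center (and back). For even n the two are
# inverses of each other only when applied in the matching order; we only
# ever use fftshift on power spectra, which are consumed in centered layout.
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(seq(fft_center(nr), nr), seq_len(fft_center(nr) - 1L))
  ci <- c(seq(fft_center(nc), nc), seq_len(fft_center(nc) - 1L))
  m[ri, ci, drop = FALSE]
}

# Signed frequency index along one axis in FFT (unshifted) order, in cycles
# per pixel: 0, 1/n, ..., then negative.
freq_axis <- function(n) {
  k <- c(0:(fft_center(n) - 1L), -(n - fft_center(n)):-1)[seq_len(n)]
  k / n
}

# Centered power spectrum |FFT|^2 of a real image.
power_spectrum <- function(m) {
  fftshift2(Mod(stats::fft(m))^2)
}

# Circular Gaussian centered on the (fft_center) pixel of an n x n frame.
gaussian_mask <- function(n, sigma_px) {
  cy <- fft_center(n); cx <- fft_center(n)
  y <- (seq_len(n) - cy)
  x <- (seq_len(n) - cx)
  r2 <- outer(y^2, x^2, "+")
  exp(-r2 / (2 * sigma_px^2))
}

# Rotation matrix acting on (x, y) column vectors, y pointing down the rows.
rot2 <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

# Precompute the bilinear gather (indices + weights) that rotates an n x n
# image by angle_deg about its fft_center pixel. Out-of-frame samples get
# weight 0 (zero fill).
rotation_map <- function(n, angle_deg) {
  ctr <- fft_center(n)
  xo <- rep(seq_len(n) - ctr, each = n)   # column offset, x
  yo <- rep(seq_len(n) - ctr, times = n)  # row offset, y
  Rinv <- rot2(-angle_deg)
  xs <- Rinv[1, 1] * xo + Rinv[1, 2] * yo + ctr
  ys <- Rinv[2, 1] * xo + Rinv[2, 2] * yo + ctr
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  idx <- function(yy, xx, w) {
    ok <- yy >= 1 & yy <= n & xx >= 1 & xx <= n
    list(i = ifelse(ok, (xx - 1L) * n + yy, 1L), w = w * ok)
  }
  list(n = n,
       p00 = idx(y0, x0, w00), p10 = idx(y0, x0 + 1, w10),
       p01 = idx(y0 + 1, x0, w01), p11 = idx(y0 + 1, x0 + 1, w11))
}

apply_rotation_map <- function(m, rmap) {
  v <- as.numeric(m)
  out <- rmap$p00$w * v[rmap$p00$i] + rmap$p10$w * v[rmap$p10$i] +
         rmap$p01$w * v[rmap$p01$i] + rmap$p11$w * v[rmap$p11$i]
  matrix(out, rmap$n, rmap$n)
}

# Rotate a square image by angle_deg about its fft_center pixel (bilinear,
# zero fill). Positive angles turn the vertical axis direction (0, 1) toward
# (−sin, cos) in (x, y-down) coordinates.
rotate_image <- function(m, angle_deg) {
  if (nrow(m) != ncol(m)) stop("rotate_image expects a square image")
  apply_rotation_map(m, rotation_map(nrow(m), angle_deg))
}

# Bilinear resampling of an arbitrary matrix onto a new pixel size.
resample_image <- function(m, scale) {
  nr <- max(2L, round(nrow(m) / scale)); nc <- max(2L, round(ncol(m) / scale))
  ys <- (seq_len(nr) - 1) * (nrow(m) - 1) / (nr - 1) + 1
  xs <- (seq_len(nc) - 1) * (ncol(m) - 1) / (nc - 1) + 1
  y0 <- pmin(floor(ys), nrow(m) - 1L); x0 <- pmin(floor(xs), ncol(m) - 1L)
  fy <- ys - y0; fx <- xs - x0
  m00 <- m[y0, x0, drop = FALSE]; m10 <- m[y0 + 1, x0, drop = FALSE]
  m01 <- m[y0, x0 + 1, drop = FALSE]; m11 <- m[y0 + 1, x0 + 1, drop = FALSE]
  wy <- matrix(fy, nr, nc); wx <- matrix(fx, nr, nc, byrow = TRUE)
  (1 - wy) * (1 - wx) * m00 + wy * (1 - wx) * m10 +
    (1 - wy) * wx * m01 + wy * wx * m11
}
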