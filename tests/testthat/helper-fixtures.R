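# Shared fixtures: benchmark-scale tracing parameters and synthetic scenes.
# Scenes are generated at 10 A/px (no further binning) so the tests stay
# fast while the tile/step geometry matches the 500 A / 80 % overlap regime.

bench_params <- function(...) {
  args <- utils::modifyList(
    list(tile_size_A = 500, overlap_pct = 80, binning_factor = 1,
         helix_width_A = 100, min_helix_len_A = 594, max_helix_len_A = 1500,
         alpha = 0.001, segment_spacing_A = 70),
    list(...))
  do.call(tracing_params, args)
}

bench_ref <- function(size_px = 50)
  synthetic_reference(helix_width_A = 100, axial_repeat_A = 50,
                      pixel_size_A = 10, size_px = size_px)

bench_scene <- function(seed, n_filaments = 10, snr = 0.1, image_A = 4000,
                        ...)
  generate_synthetic_scene(n_filaments = n_filaments, snr = snr,
                           image_A = image_A, pixel_size_A = 10,
                           helix_width_A = 100, axial_repeat_A = 50,
                           seed = seed, ...)

# independent 8-connected component counter (simple two-pass-free flood
# fill on index sets; deliberately separate from the package internals)
oracle_n_components <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  seen <- matrix(FALSE, nr, nc)
  n <- 0L
  for (start in which(binary & !seen)) {
    if (seen[start]) next
    n <- n + 1L
    stack <- start
    seen[start] <- TRUE
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      py <- (p - 1L) %% nr + 1L; px <- (p - 1L) %/% nr + 1L
      for (dy in -1:1) for (dx in -1:1) {
        yy <- py + dy; xx <- px + dx
        if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc &&
            binary[yy, xx] && !seen[yy, xx]) {
          seen[yy, xx] <- TRUE
          stack <- c(stack, (xx - 1L) * nr + yy)
        }
      }
    }
  }
  n
}

# random blobby binary image for skeleton property tests
random_blobs <- function(seed, n = 60, blobs = 5) {
  set.seed(seed)
  img <- matrix(FALSE, n, n)
  for (b in seq_len(blobs)) {
    cy <- sample(8:(n - 8), 1); cx <- sample(8:(n - 8), 1)
    r <- sample(3:7, 1)
    d2 <- outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, "+")
    img <- img | d2 <= r^2
  }
  img
}

# ring bits (N, NE, E, SE, S, SW, W, NW) of a skeleton pixel, 1-based index
ring_bits_at <- function(m, y, x) {
  off <- cbind(c(-1, -1, 0, 1, 1, 1, 0, -1), c(0, 1, 1, 1, 0, -1, -1, -1))
  vapply(1:8, function(i) {
    yy <- y + off[i, 1]; xx <- x + off[i, 2]
    if (yy < 1 || yy > nrow(m) || xx < 1 || xx > ncol(m)) 0L
    else as.integer(m[yy, xx])
  }, integer(1))
}

# number of maximal cyclic runs of set ring positions
oracle_ring_runs <- function(bits) {
  if (all(bits == 0)) return(0L)
  if (all(bits == 1)) return(1L)
  sum(bits == 1 & c(bits[8], bits[1:7]) == 0)
}
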