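# Continuous cross-correlation map: per-tile matches are drawn back into a
# micrograph-shaped map as cc-intensity line segments; tiles containing a
# helix reinforce each other additively along its path while noise tiles,
# with random angles and shifts, do not build up coherent lines.

#' Accumulate tile matches into a correlation map
#'
#' For every tile match, a line segment of tile length at angle `theta`,
#' displaced by `delta` from the tile center along the axis normal, is added
#' to the map with amplitude `cc_score`, a Gaussian falloff of
#' `sigma = 2 * step` along the line from the adjusted center (so that helix
#' start and end positions taper off rather than ending abruptly), and a
#' narrow transverse profile (`sigma_perp`, two pixels) across it; the line
#' is truncated at half the tile size along the axis. Contributions add.
#' Lines must stay narrow: they cover only a small fraction of the map, so
#' the background histogram keeps its exponential falloff from zero and the
#' significance thresholding stays calibrated, while the lines of the tiles
#' that share a helix pile up along its path. Matches with non-positive
#' cc-score draw nothing.
#'
#' @param matches `tile_matches` from [match_all_tiles()].
#' @param grid the `tile_grid` the matches were computed on.
#' @param shape (rows, cols) of the working image.
#' @param sigma_perp_px transverse Gaussian width of the drawn line.
#' @return object of class `correlation_map`: list with `values` (matrix >= 0)
#'   and `line_sigma_px` (the longitudinal falloff).
#' @export
accumulate_map <- function(matches, grid, shape, sigma_perp_px = 2) {
  vals <- matrix(0, shape[1], shape[2])
  sigma <- 2 * grid$step_px
  half_len <- grid$tile_size_px / 2
  c0 <- floor(grid$tile_size_px / 2)  # tile center offset, 0-based
  reach <- ceiling(3 * sigma_perp_px)
  for (i in seq_len(nrow(matches))) {
    cc <- matches$cc_score[i]
    if (cc <= 0) next
    th <- matches$theta_deg[i] * pi / 180
    a <- c(-sin(th), cos(th))   # axis direction (x, y-down)
    nv <- c(cos(th), sin(th))   # axis normal
    org <- grid$origins[matches$tile_index[i], ]
    cx <- org[2] + c0 + matches$delta_px[i] * nv[1]
    cy <- org[1] + c0 + matches$delta_px[i] * nv[2]
    x0 <- max(0, floor(cx - half_len - reach))
    x1 <- min(shape[2] - 1, ceiling(cx + half_len + reach))
    y0 <- max(0, floor(cy - half_len - reach))
    y1 <- min(shape[1] - 1, ceiling(cy + half_len + reach))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
    dy <- matrix(ys - cy, length(ys), length(xs))
    t_along <- dx * a[1] + dy * a[2]
    t_perp <- dx * nv[1] + dy * nv[2]
    contrib <- cc * exp(-t_perp^2 / (2 * sigma_perp_px^2) -
                          t_along^2 / (2 * sigma^2)) *
      (abs(t_along) <= half_len) * (abs(t_perp) <= reach)
    vals[ys + 1, xs + 1] <- vals[ys + 1, xs + 1] + contrib
  }
  structure(list(values = vals, line_sigma_px = sigma),
            class = "correlation_map")
}

#' Fit the exponential null distribution of map values
#'
#' In helix-free regions the correlation-map values follow an exponential
#' falloff; the few high values along helix paths sit in the tail. The scale
#' is estimated robustly from the median of the non-zero values (the median
#' of an exponential with scale `s` is `s * ln 2`), so the estimate is barely
#' affected by the helix tail.
#'
#' @param map a `correlation_map` (or numeric matrix/vector of map values).
#' @return object of class `exponential_null` with field `lambda_scale`.
#' @export
fit_null <- function(map) {
  vals <- if (inherits(map, "correlation_map")) map$values else map
  nz <- vals[vals > 0]
  if (length(nz) <= 100)
    stop("too few non-zero map values (", length(nz), ") to fit the null")
  structure(list(lambda_scale = stats::median(nz) / log(2)),
            class = "exponential_null")
}

#' Threshold the correlation map against the fitted null
#'
#' A pixel passes when its upper-tail p-value under the exponential null,
#' `exp(-x / lambda)`, is below `alpha`; equivalently when its value exceeds
#' `lambda * ln(1/alpha)`. Zero pixels never pass. An `alpha` of 0.001 can be
#' read as a 0.1 percent risk of a false-positive trace pixel where no helix
#' exists.
#'
#' @param map a `correlation_map` (or numeric matrix).
#' @param null an `exponential_null` from [fit_null()].
#' @param alpha significance level in (0, 1].
#' @return logical matrix of passing pixels.
#' @export
threshold_map <- function(map, null, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  vals <- if (inherits(map, "correlation_map")) map$values else map
  cutoff <- null$lambda_scale * log(1 / alpha)
  vals > cutoff & vals > 0
}
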