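make_grid <- function(shape = c(100, 100), tile_A = 250, pixel_A = 10) {
  make_tile_grid(shape, tracing_params(tile_size_A = tile_A), pixel_A)
}

match_row <- function(idx, theta, delta, cc)
  structure(data.frame(tile_index = idx, theta_deg = theta, delta_px = delta,
                       cc_score = cc), class = c("tile_matches", "data.frame"))

test_that("map accumulation draws Gaussian-falloff lines where matches say", {
  g <- make_grid()  # 25 px tiles, 5 px step
  empty <- accumulate_map(match_row(integer(0), numeric(0), numeric(0),
                                    numeric(0)), g, c(100, 100))
  expect_true(all(empty$values == 0))
  expect_equal(empty$line_sigma_px, 2 * g$step_px)
  # single vertical match centered on its tile
  m1 <- accumulate_map(match_row(1L, 0, 0, 1), g, c(100, 100))
  ctr <- floor(g$tile_size_px / 2)  # 0-based center of tile at origin (0,0)
  peak <- m1$values[ctr + 1, ctr + 1]
  expect_equal(peak, max(m1$values))
  expect_equal(peak, 1)
  # transverse decay (x direction for a vertical line), sigma_perp = 2
  expect_equal(m1$values[ctr + 1, ctr + 3], exp(-4 / (2 * 4)), tolerance = 1e-9)
  # longitudinal decay with sigma = 2 * step = 10
  expect_equal(m1$values[ctr + 5, ctr + 1], exp(-16 / (2 * 100)),
               tolerance = 1e-9)
  # truncation at half a tile length along the axis
  expect_equal(m1$values[ctr + 14, ctr + 1], 0)
})

test_that("collinear matches in adjacent tiles reinforce additively", {
  g <- make_grid()
  # two vertically adjacent tiles sharing a vertical filament at x = 12
  og <- g$origins
  i1 <- which(og[, "row"] == 0 & og[, "col"] == 0)[1]
  i2 <- which(og[, "row"] == g$step_px & og[, "col"] == 0)[1]
  both <- accumulate_map(match_row(c(i1, i2), c(0, 0), c(0, 0), c(1, 1)),
                         g, c(100, 100))
  one <- accumulate_map(match_row(i1, 0, 0, 1), g, c(100, 100))
  two <- accumulate_map(match_row(i2, 0, 0, 1), g, c(100, 100))
  mid <- c(floor(g$tile_size_px / 2) + floor(g$step_px / 2) + 1,
           floor(g$tile_size_px / 2) + 1)
  expect_equal(both$values, one$values + two$values)
  expect_gt(both$values[mid[1], mid[2]], one$values[mid[1], mid[2]])
  expect_gt(both$values[mid[1], mid[2]], two$values[mid[1], mid[2]])
})

test_that("negative-score matches draw nothing", {
  g <- make_grid()
  m <- accumulate_map(match_row(1L, 45, 2, -0.3), g, c(100, 100))
  expect_true(all(m$values == 0))
})

test_that("exponential null fit recovers the scale from the median", {
  vals <- matrix(0, 20, 20)
  vals[1:200] <- 3.5
  expect_equal(fit_null(vals)$lambda_scale, 3.5 / log(2))
  expect_error(fit_null(matrix(c(rep(0, 395), rep(1, 5)), 20, 20)),
               "too few")
  set.seed(12)
  draws <- matrix(rexp(1e6, rate = 1 / 2), 1000, 1000)
  expect_equal(fit_null(draws)$lambda_scale, 2, tolerance = 0.01)
  # 5% gross outliers: the median moves only to the 52.6th percentile of
  # the clean distribution, so the estimate shifts by ~8%, not 100x
  contaminated <- draws
  contaminated[1:5e4] <- contaminated[1:5e4] * 100
  shifted_median <- 2 * -log(1 - 0.5 / 0.95)  # exact for Exp(2)
  expect_equal(fit_null(contaminated)$lambda_scale, shifted_median / log(2),
               tolerance = 0.01)
  expect_lt(abs(fit_null(contaminated)$lambda_scale - 2) / 2, 0.1)
})

test_that("thresholding implements the exponential upper-tail p-value", {
  null <- structure(list(lambda_scale = 1), class = "exponential_null")
  vals <- matrix(c(0, 6.90, 6.91, 100), 2, 2)
  pass <- threshold_map(vals, null, alpha = 0.001)  # cutoff ln(1000) = 6.9078
  expect_equal(as.vector(pass), c(FALSE, FALSE, TRUE, TRUE))
  # alpha = 1: every non-zero pixel passes
  expect_equal(as.vector(threshold_map(vals, null, 1)),
               c(FALSE, TRUE, TRUE, TRUE))
  # monotonicity: smaller alpha always passes a subset
  set.seed(13)
  vals2 <- matrix(rexp(1e4), 100, 100)
  null2 <- fit_null(vals2)
  p1 <- threshold_map(vals2, null2, 0.001)
  p2 <- threshold_map(vals2, null2, 0.05)
  expect_true(all(p2[p1]))
})

test_that("skeletonization thins bars to centered unit-width paths", {
  bar <- matrix(FALSE, 20, 60)
  bar[8:12, 10:49] <- TRUE  # 5 px wide, 40 px long
  sk <- skeletonize(bar)
  expect_s3_class(sk, "skeleton_map")
  on <- which(unclass(sk), arr.ind = TRUE)
  expect_true(all(on[, 1] == 10))            # centered row
  expect_lte(abs(min(on[, 2]) - 10), 3)      # endpoints near bar ends
  expect_lte(abs(max(on[, 2]) - 49), 3)
  expect_false(any(unclass(sk) & !bar))  # subset of input
  # idempotent on thin input
  expect_equal(unclass(skeletonize(unclass(sk))), unclass(sk))
})

test_that("thinning preserves 8-connected component count and thinness", {
  for (seed in 1:20) {
    img <- random_blobs(seed)
    sk <- unclass(skeletonize(img))
    expect_identical(oracle_n_components(sk), oracle_n_components(img))
    expect_true(all(sk[!img] == FALSE))  # subset
    blk <- sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
      sk[-nrow(sk), -1] & sk[-1, -1]
    expect_false(any(blk))  # no fully set 2x2 block
  }
})

test_that("branch template enumeration matches the junction taxonomy", {
  bt <- branch_templates()
  # seven unique three-branch tiles up to rotation and mirroring
  expect_length(bt$canonical, 7)
  # the two four-branch crossings: '+' and 'X'
  expect_length(bt$canonical_crossings, 2)
  plus <- matrix(0L, 3, 3); plus[2, ] <- 1L; plus[, 2] <- 1L
  xx <- diag(3) * 0L; xx <- matrix(0L, 3, 3)
  xx[c(1, 5, 9, 3, 7)] <- 1L
  expect_true(any(vapply(bt$canonical_crossings, identical, logical(1), plus)))
  expect_true(any(vapply(bt$canonical_crossings, identical, logical(1), xx)))
  # straight-line neighborhoods (2 runs) are not templates
  line_code <- 256L + 2L^2 + 2L^6  # E + W neighbors
  expect_false(line_code %in% bt$codes)
  # every code corresponds to >= 3 emanating runs and <= 4 neighbors
  for (i in seq_len(nrow(bt$ring_patterns))) {
    bits <- bt$ring_patterns[i, ]
    expect_gte(oracle_ring_runs(bits), 3)
    expect_lte(sum(bits), 4)
  }
})

test_that("branch detection equals direct run counting on random skeletons", {
  templates <- branch_templates()
  for (seed in 21:40) {
    sk <- unclass(skeletonize(random_blobs(seed, blobs = 6)))
    found <- detect_branch_points(structure(sk, class = "skeleton_map"),
                                  templates)
    found_key <- as.integer(sort(found[, 1] * 1000 + found[, 2]))
    expected <- integer(0)
    for (idx in which(sk)) {
      y <- (idx - 1) %% nrow(sk) + 1; x <- (idx - 1) %/% nrow(sk) + 1
      bits <- ring_bits_at(sk, y, x)
      if (oracle_ring_runs(bits) >= 3 && sum(bits) <= 4)
        expected <- c(expected, (y - 1) * 1000 + (x - 1))
    }
    expect_equal(found_key, as.integer(sort(expected)))
  }
})

test_that("branch detection flags crossings and spares simple paths", {
  plus <- matrix(FALSE, 11, 11); plus[6, 2:10] <- TRUE; plus[2:10, 6] <- TRUE
  bp <- detect_branch_points(structure(plus, class = "skeleton_map"))
  expect_equal(nrow(bp), 1)
  expect_equal(unname(bp[1, ]), c(5, 5))  # 0-based center
  curve <- matrix(FALSE, 15, 15)
  for (x in 1:14) curve[round(8 + 4 * sin(x / 4)), x] <- TRUE
  curve <- unclass(skeletonize(curve))
  expect_equal(nrow(detect_branch_points(
    structure(curve, class = "skeleton_map"))), 0)
})

test_that("branch erasure splits crossings into separate arms", {
  plus <- matrix(FALSE, 31, 31); plus[16, ] <- TRUE; plus[, 16] <- TRUE
  skel <- structure(plus, class = "skeleton_map")
  bp <- detect_branch_points(skel)
  # helix width 10 px at 1 A/px: clears radius 5 around the center
  out <- erase_branch_regions(skel, bp, helix_width_A = 10, pixel_size_A = 1)
  expect_equal(oracle_n_components(unclass(out)), 4)
  # no branch points: identity
  expect_equal(unclass(erase_branch_regions(skel, bp[0, , drop = FALSE],
                                            10, 1)), plus)
})

test_that("an X-crossing of two synthetic traces yields four arms", {
  img <- matrix(FALSE, 41, 41)
  for (k in 1:41) { img[k, k] <- TRUE; img[k, 42 - k] <- TRUE }
  skel <- skeletonize(img)
  bp <- detect_branch_points(skel)
  expect_gte(nrow(bp), 1)
  out <- erase_branch_regions(skel, bp, helix_width_A = 8, pixel_size_A = 1)
  expect_equal(oracle_n_components(unclass(out)), 4)
})

test_that("path extraction orders pixels and measures contour length", {
  line <- matrix(FALSE, 10, 50); line[5, 5:45] <- TRUE  # 41 px
  paths <- extract_paths(structure(line, class = "skeleton_map"))
  expect_length(paths, 1)
  expect_equal(nrow(paths[[1]]), 41)
  expect_equal(helixtracer:::path_contour_px(paths[[1]]), 40)
  diag <- matrix(FALSE, 50, 50)
  for (k in 5:45) diag[k, k] <- TRUE  # 41 px staircase-free diagonal
  pd <- extract_paths(structure(diag, class = "skeleton_map"))
  expect_equal(helixtracer:::path_contour_px(pd[[1]]), 40 * sqrt(2))
  # consecutive path pixels are always 8-neighbors, on random skeletons
  for (seed in 41:50) {
    sk <- skeletonize(random_blobs(seed, blobs = 4))
    sk <- erase_branch_regions(sk, detect_branch_points(sk), 6, 1)
    for (p in extract_paths(sk)) {
      if (nrow(p) < 2) next
      steps <- abs(diff(p))
      expect_true(all(steps <= 1) && all(rowSums(steps) >= 1))
    }
  }
})

test_that("closed loops are cut and flagged; live branches are an error", {
  ring <- matrix(FALSE, 21, 21)
  th <- seq(0, 2 * pi, length.out = 200)
  ring[cbind(round(11 + 7 * sin(th)), round(11 + 7 * cos(th)))] <- TRUE
  ring <- unclass(skeletonize(ring))
  paths <- extract_paths(structure(ring, class = "skeleton_map"))
  expect_length(paths, 1)
  expect_true(isTRUE(attr(paths[[1]], "loop")))
  expect_equal(nrow(paths[[1]]), sum(ring))
  plus <- matrix(FALSE, 11, 11); plus[6, 2:10] <- TRUE; plus[2:10, 6] <- TRUE
  expect_error(extract_paths(structure(plus, class = "skeleton_map")),
               "branch")
})
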