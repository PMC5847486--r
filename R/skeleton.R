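# Skeletonization of the binarized correlation map and splitting of crossing
# helices at branch points. Thinning reduces each thresholded ridge to a
# one-pixel-wide 8-connected path without separating connected components;
# branch points (where >= 3 paths meet) mark filament crossings and are
# erased with a helix-width disc so the crossing helices fall apart into
# separate components.

# shift a logical/numeric matrix by (dy, dx) with zero fill
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(ys) && length(xs))
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

# 8-neighborhood ring in clockwise order starting North, as (dy, dx) of the
# *neighbor relative to the center*: N, NE, E, SE, S, SW, W, NW.
RING_OFFSETS <- cbind(dy = c(-1, -1, 0, 1, 1, 1, 0, -1),
                      dx = c(0, 1, 1, 1, 0, -1, -1, -1))

# neighbor count maps P2..P9 (N, NE, E, SE, S, SW, W, NW) for a 0/1 matrix;
# shift_mat(m, -dy, -dx) places the neighbor's value at the center pixel
ring_neighbors <- function(m) {
  lapply(seq_len(8), function(i)
    shift_mat(m, -RING_OFFSETS[i, 1], -RING_OFFSETS[i, 2]))
}

#' Morphological thinning to a one-pixel skeleton
#'
#' Iterative two-subiteration thinning (Guo-Hall) that removes boundary
#' pixels until each region is one pixel wide, while preserving
#' 8-connectivity of components. Idempotent on already-thin input.
#'
#' @param binary logical (or 0/1) matrix.
#' @return object of class `skeleton_map`: logical matrix attribute-tagged
#'   with its provenance.
#' @export
skeletonize <- function(binary) {
  m <- matrix(as.numeric(binary != 0), nrow(binary), ncol(binary))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- ring_neighbors(m)
      p2 <- nb[[1]]; p3 <- nb[[2]]; p4 <- nb[[3]]; p5 <- nb[[4]]
      p6 <- nb[[5]]; p7 <- nb[[6]]; p8 <- nb[[7]]; p9 <- nb[[8]]
      C <- (1 - p2) * pmax(p3, p4) + (1 - p4) * pmax(p5, p6) +
           (1 - p6) * pmax(p7, p8) + (1 - p8) * pmax(p9, p2)
      N1 <- pmax(p9, p2) + pmax(p3, p4) + pmax(p5, p6) + pmax(p7, p8)
      N2 <- pmax(p2, p3) + pmax(p4, p5) + pmax(p6, p7) + pmax(p8, p9)
      N <- pmin(N1, N2)
      m_cond <- if (sub == 1) pmax(p6, p7, 1 - p9) * p8
                else pmax(p2, p3, 1 - p5) * p4
      del <- m == 1 & C == 1 & N >= 2 & N <= 3 & m_cond == 0
      if (any(del)) { m[del] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  structure(m == 1, class = "skeleton_map")
}

# count of maximal cyclic runs of set positions in an 8-bit ring pattern
ring_runs <- function(bits) {
  if (all(bits == 0)) return(0L)
  if (all(bits == 1)) return(1L)
  # number of 0->1 transitions around the cycle
  sum(bits == 1 & c(bits[8], bits[1:7]) == 0)
}

#' Branch-point neighborhood templates
#'
#' Enumerates all 3x3 neighborhoods (center set) that constitute a branch
#' point on a thinned skeleton. Grouping the 8 ring neighbors into maximal
#' runs of cyclically consecutive set positions (one run = one emanating
#' path), a branch point has at least 3 runs and at most 4 set neighbors (5
#' or more cannot survive thinning). Exhaustive enumeration reduces the
#' three-branch neighborhoods (T- and Y-junctions, where crossing filaments
#' almost always meet after thinning) to exactly seven unique tiles up to
#' the 4 rotations by 90 degrees and mirroring; the two four-branch
#' crossings ('+' and 'X') complete the lookup set. The full set used for
#' detection expands every template by its 4 rotations and mirrored
#' versions, duplicates removed.
#'
#' @return list with `canonical` (the seven unique three-branch 3x3 0/1
#'   matrices, up to rotation and mirroring), `canonical_crossings` (the two
#'   four-branch patterns), `codes` (integer convolution responses of the
#'   full expanded set, see [detect_branch_points()]) and `ring_patterns`
#'   (8-column 0/1 matrix of the expanded set).
#' @export
branch_templates <- function() {
  rot90_ring <- function(bits) c(bits[7:8], bits[1:6])  # rotate by 90 deg
  mirror_ring <- function(bits) bits[c(1, 8, 7, 6, 5, 4, 3, 2)]  # flip E-W
  is_branch <- function(bits) ring_runs(bits) >= 3 && sum(bits) <= 4
  all_bits <- t(sapply(0:255, function(k) as.integer(intToBits(k)[1:8])))
  keep <- apply(all_bits, 1, is_branch)
  ring_key <- function(bits) sum(bits * 2^(0:7))
  canon_key <- function(bits) {
    ks <- numeric(8)
    for (m in 0:1) {
      b <- if (m) mirror_ring(bits) else bits
      for (i in 1:4) { ks[4 * m + i] <- ring_key(b); b <- rot90_ring(b) }
    }
    min(ks)
  }
  as_tile <- function(bits) {
    m <- matrix(0L, 3, 3); m[2, 2] <- 1L
    for (j in 1:8) m[RING_OFFSETS[j, 1] + 2, RING_OFFSETS[j, 2] + 2] <- bits[j]
    m
  }
  cand <- all_bits[keep, , drop = FALSE]
  nbr <- rowSums(cand)
  nruns <- apply(cand, 1, ring_runs)
  keys <- apply(cand, 1, canon_key)
  pick_canonical <- function(rows) {
    sub <- cand[rows, , drop = FALSE]
    k <- keys[rows]
    reps <- sub[!duplicated(k), , drop = FALSE]
    reps <- reps[order(k[!duplicated(k)]), , drop = FALSE]
    lapply(seq_len(nrow(reps)), function(i) as_tile(reps[i, ]))
  }
  canonical <- pick_canonical(which(nruns == 3))
  crossings <- pick_canonical(which(nruns >= 4))
  # expand all branch patterns by 4 rotations and mirrors, deduplicate
  expanded <- list()
  for (i in seq_len(nrow(cand))) {
    b <- cand[i, ]
    for (mir in 0:1) {
      bb <- if (mir) mirror_ring(b) else b
      for (r in 1:4) { expanded[[length(expanded) + 1]] <- bb; bb <- rot90_ring(bb) }
    }
  }
  expanded <- unique(expanded)
  ring_patterns <- do.call(rbind, expanded)
  codes <- as.integer(ring_patterns %*% 2^(0:7)) + 256L  # center = bit 8
  list(canonical = canonical, canonical_crossings = crossings,
       codes = sort(codes), ring_patterns = ring_patterns)
}

# neighborhood code map: each position weighted 2^n (ring bits 0..7 in the
# RING_OFFSETS order, center = bit 8), so every pixel receives a unique
# integer in [0, 511]
neighborhood_codes <- function(skel) {
  m <- matrix(as.numeric(skel), nrow(skel), ncol(skel))
  code <- 256 * m
  for (i in seq_len(8))
    code <- code + 2^(i - 1) *
      shift_mat(m, -RING_OFFSETS[i, 1], -RING_OFFSETS[i, 2])
  code
}

#' Detect branch points on a skeleton
#'
#' Convolves the binary skeleton with a 3x3 kernel of powers of two so that
#' every pixel's neighborhood maps to a unique code in `[0, 511]`, then looks
#' the codes up in the precomputed branch-template set.
#'
#' @param skel a `skeleton_map` (or logical matrix).
#' @param templates result of [branch_templates()] (computed if missing).
#' @return integer matrix with columns `row`, `col` (0-based) of branch
#'   points.
#' @export
detect_branch_points <- function(skel, templates = branch_templates()) {
  code <- neighborhood_codes(skel)
  hit <- matrix(code %in% templates$codes, nrow(code), ncol(code)) & skel
  w <- which(hit, arr.ind = TRUE)
  cbind(row = w[, 1] - 1L, col = w[, 2] - 1L)
}

#' Erase circular regions around branch points
#'
#' Clears a circular area of helix diameter (radius = half the helix width)
#' around every branch point, so crossing helices separate into independent
#' components. The overlap region itself is discarded (no re-linking across
#' the crossing).
#'
#' @param skel a `skeleton_map`.
#' @param points branch points from [detect_branch_points()].
#' @param helix_width_A helix width in Angstrom.
#' @param pixel_size_A working pixel size.
#' @return pruned `skeleton_map`.
#' @export
erase_branch_regions <- function(skel, points, helix_width_A, pixel_size_A) {
  if (is.null(points) || nrow(points) == 0) return(skel)
  r <- helix_width_A / 2 / pixel_size_A
  m <- unclass(skel)
  on <- which(m, arr.ind = TRUE)
  if (nrow(on)) {
    for (i in seq_len(nrow(points))) {
      d2 <- (on[, 1] - 1 - points[i, 1])^2 + (on[, 2] - 1 - points[i, 2])^2
      kill <- on[d2 <= r^2, , drop = FALSE]
      if (nrow(kill)) m[kill] <- FALSE
    }
  }
  structure(m, class = "skeleton_map")
}

# 8-connected component labels of a logical matrix (two-pass not needed at
# our sizes; simple queue-based flood fill)
label_components <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(binary)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      py <- (p - 1L) %% nr + 1L; px <- (p - 1L) %/% nr + 1L
      for (dy in -1:1) for (dx in -1:1) {
        yy <- py + dy; xx <- px + dx
        if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc &&
            binary[yy, xx] && lab[yy, xx] == 0L) {
          q <- (xx - 1L) * nr + yy
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Extract ordered pixel paths from a branch-free skeleton
#'
#' Returns every 8-connected component as an ordered coordinate sequence from
#' one endpoint to the other. Closed loops are cut at an arbitrary pixel and
#' flagged with attribute `loop`. Components containing a pixel with three or
#' more skeleton neighbors are an error: branch removal must run first.
#'
#' @param skel a branch-free `skeleton_map`.
#' @return list of integer matrices with columns `row`, `col` (0-based),
#'   ordered so that consecutive pixels are 8-neighbors.
#' @export
extract_paths <- function(skel) {
  m <- unclass(skel)
  lab <- label_components(m)
  ncomp <- max(lab)
  nr <- nrow(m)
  # neighbor degree within the skeleton
  deg <- matrix(0, nr, ncol(m))
  for (i in seq_len(8))
    deg <- deg + shift_mat(m, -RING_OFFSETS[i, 1], -RING_OFFSETS[i, 2])
  deg[!m] <- 0
  # a pixel with >= 3 emanating runs is an unhandled branch; raw degree 3
  # with an adjacent neighbor pair (one run) is a normal staircase corner
  if (any(deg[m] >= 3)) {
    codes <- neighborhood_codes(m)
    high <- which(m & deg >= 3)
    bad <- vapply(high, function(i) {
      bits <- as.integer(intToBits(as.integer(codes[i]))[1:8])
      ring_runs(bits) >= 3
    }, logical(1))
    if (any(bad))
      stop("skeleton contains a branching pixel; ",
           "run branch-point removal first")
  }
  paths <- vector("list", ncomp)
  for (k in seq_len(ncomp)) {
    members <- which(lab == k)
    if (length(members) == 1) {
      py <- (members - 1L) %% nr + 1L; px <- (members - 1L) %/% nr + 1L
      paths[[k]] <- cbind(row = py - 1L, col = px - 1L)
      next
    }
    ends <- members[deg[members] == 1]
    loop <- length(ends) == 0
    start <- if (loop) members[1] else ends[1]
    visited <- rep(FALSE, length(members))
    names(visited) <- members
    path <- integer(length(members))
    path[1] <- start
    visited[as.character(start)] <- TRUE
    cur <- start
    for (step in seq_len(length(members) - 1L)) {
      py <- (cur - 1L) %% nr + 1L; px <- (cur - 1L) %/% nr + 1L
      nxt <- NA_integer_
      best_d2 <- Inf
      for (i in seq_len(8)) {
        yy <- py + RING_OFFSETS[i, 1]; xx <- px + RING_OFFSETS[i, 2]
        if (yy < 1 || yy > nr || xx < 1 || xx > ncol(m)) next
        q <- (xx - 1L) * nr + yy
        if (m[yy, xx] && !isTRUE(visited[as.character(q)])) {
          # prefer orthogonal over diagonal steps so staircases stay ordered
          d2 <- RING_OFFSETS[i, 1]^2 + RING_OFFSETS[i, 2]^2
          if (d2 < best_d2) { nxt <- q; best_d2 <- d2 }
        }
      }
      if (is.na(nxt)) break
      path[step + 1L] <- nxt
      visited[as.character(nxt)] <- TRUE
      cur <- nxt
    }
    path <- path[path != 0L]
    py <- (path - 1L) %% nr + 1L; px <- (path - 1L) %/% nr + 1L
    out <- cbind(row = py - 1L, col = px - 1L)
    if (loop) attr(out, "loop") <- TRUE
    paths[[k]] <- out
  }
  paths
}

# contour length of a pixel path in pixels (1 orthogonal, sqrt(2) diagonal)
path_contour_px <- function(path) {
  if (nrow(path) < 2) return(0)
  d <- sqrt(rowSums(diff(path)^2))
  sum(d)
}
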