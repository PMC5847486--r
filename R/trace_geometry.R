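# From pixel paths to helix traces: length filtering/splitting, polynomial
# fitting with equidistant arc-length resampling, per-trace flexibility and
# persistence length, and population-level pruning of over-bent traces.

#' Filter short paths and split over-long ones
#'
#' Paths shorter than the minimum helix length are discarded (they usually
#' correspond to contamination or noise); paths longer than the maximum are
#' split into the smallest number of near-equal pieces not exceeding it, so
#' all traces carry a comparable stiffness restraint in the later polynomial
#' fit.
#'
#' @param paths list of pixel paths (0-based `row`,`col` matrices).
#' @param min_len_A,max_len_A length window in Angstrom (inclusive minimum).
#' @param pixel_size_A working pixel size.
#' @return filtered list of pixel paths.
#' @export
filter_and_split <- function(paths, min_len_A, max_len_A, pixel_size_A) {
  stopifnot(min_len_A < max_len_A)
  out <- list()
  for (p in paths) {
    L <- path_contour_px(p) * pixel_size_A
    if (L < min_len_A) next
    if (L <= max_len_A) { out[[length(out) + 1]] <- p; next }
    npieces <- ceiling(L / max_len_A)
    cum <- c(0, cumsum(sqrt(rowSums(diff(p)^2)))) * pixel_size_A
    cuts <- seq(0, L, length.out = npieces + 1)
    for (k in seq_len(npieces)) {
      sel <- cum >= cuts[k] & cum <= cuts[k + 1] + 1e-9
      piece <- p[sel, , drop = FALSE]
      if (nrow(piece) >= 2) out[[length(out) + 1]] <- piece
    }
  }
  out
}

#' Fit a polynomial trace through a pixel path
#'
#' Rotates the path into its principal-axis frame (so the curve is a
#' single-valued function even for near-vertical helices), fits a least-
#' squares polynomial, and resamples the fitted curve at equal arc-length
#' steps. Polynomial order defaults by trace length: linear below 500 A,
#' quadratic between 500 and 2000 A (sufficient even for flexible polymers
#' at these lengths), cubic above.
#'
#' @param path pixel path (0-based `row`,`col` matrix).
#' @param pixel_size_A working pixel size in Angstrom.
#' @param order polynomial order 1-3, or NULL for length-based default.
#' @param segment_spacing_A arc-length spacing of output coordinates.
#' @param micrograph_id provenance label.
#' @return object of class `helix_trace`: list with `coords_A` (matrix of
#'   `x`,`y` in Angstrom), contour length `L_A`, end-to-end distance `R_A`,
#'   flexibility `lambda` (1/A), persistence length `p_A`, `poly_order`,
#'   `flexible_flag` (TRUE when R/L is outside the estimator's domain) and
#'   `micrograph_id`.
#' @export
fit_trace <- function(path, pixel_size_A, order = NULL,
                      segment_spacing_A = 70, micrograph_id = "unknown") {
  xy <- cbind(x = path[, "col"], y = path[, "row"]) * pixel_size_A
  L_raw <- path_contour_px(path) * pixel_size_A
  if (is.null(order))
    order <- if (L_raw < 500) 1L else if (L_raw <= 2000) 2L else 3L
  order <- as.integer(order)
  stopifnot(order >= 1, order <= 3)
  if (nrow(xy) < order + 1)
    stop("path has ", nrow(xy), " points; order-", order,
         " fit needs at least ", order + 1)
  ctr <- colMeans(xy)
  xc <- sweep(xy, 2, ctr)
  # principal axis: fit along the dominant direction
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)$vectors
  u <- as.numeric(xc %*% ev[, 1]); v <- as.numeric(xc %*% ev[, 2])
  # orient u along the path so resampling preserves the original ordering
  if (u[length(u)] < u[1]) { u <- -u; ev[, 1] <- -ev[, 1] }
  cf <- unname(stats::lm.fit(outer(u, 0:order, "^"), v)$coefficients)
  cf[is.na(cf)] <- 0
  poly_v <- function(uu) {
    acc <- rep(cf[1], length(uu))
    for (k in seq_len(order)) acc <- acc + cf[k + 1] * uu^k
    acc
  }
  # dense sampling for arc length
  ud <- seq(min(u), max(u), length.out = max(200L, 50L * order))
  vd <- poly_v(ud)
  seg <- sqrt(diff(ud)^2 + diff(vd)^2)
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  s_out <- seq(0, L, by = segment_spacing_A)
  if (s_out[length(s_out)] < L) s_out <- c(s_out, L)
  u_out <- stats::approx(arc, ud, xout = s_out, ties = "ordered")$y
  v_out <- poly_v(u_out)
  coords <- cbind(u_out, v_out) %*% t(ev)
  coords <- sweep(coords, 2, ctr, "+")
  colnames(coords) <- c("x", "y")
  R <- sqrt(sum((coords[nrow(coords), ] - coords[1, ])^2))
  R <- min(R, L)  # guard against dense-sampling roundoff
  fp <- flexibility_and_persistence(R, L)
  structure(list(coords_A = coords, L_A = L, R_A = R,
                 lambda = fp$lambda, p_A = fp$p,
                 flexible_flag = fp$flagged, poly_order = order,
                 micrograph_id = micrograph_id),
            class = "helix_trace")
}

#' Per-trace flexibility and persistence length
#'
#' The flexibility of a single trace is estimated from its end-to-end
#' distance `R` and contour length `L` by the closed-form approximation
#' `lambda = -ln(2 (R/L)^2 - 1) / L`; the persistence length is `p = 1 /
#' lambda`. For `R/L <= 1/sqrt(2)` the logarithm's argument is non-positive
#' and the trace is flagged maximally flexible (`p = 0` sentinel, always
#' prunable). A perfectly straight trace (`R = L`) gives `lambda = 0`,
#' `p = Inf` (rigid-rod sentinel).
#'
#' @param R_A end-to-end distance in Angstrom.
#' @param L_A contour length in Angstrom.
#' @return list with `lambda` (1/A), `p` (A) and `flagged`.
#' @export
flexibility_and_persistence <- function(R_A, L_A) {
  if (R_A > L_A) stop("end-to-end distance exceeds contour length")
  if (R_A <= 0 || L_A <= 0) stop("R and L must be positive")
  arg <- 2 * (R_A / L_A)^2 - 1
  if (arg <= 0)
    return(list(lambda = NA_real_, p = 0, flagged = TRUE))
  lambda <- -log(arg) / L_A
  p <- if (lambda == 0) Inf else 1 / lambda
  list(lambda = lambda, p = p, flagged = FALSE)
}

#' Bundle helix traces into a trace set
#'
#' @param traces list of `helix_trace` objects.
#' @return object of class `trace_set` with population statistics of
#'   `ln(p)` (median and 1.4826*MAD over traces with finite positive `p`).
#' @export
trace_set <- function(traces = list()) {
  ts <- structure(list(traces = traces,
                       population_median_log_p = NA_real_,
                       population_mad_log_p = NA_real_),
                  class = "trace_set")
  refresh_stats(ts)
}

refresh_stats <- function(ts) {
  p <- vapply(ts$traces, function(t) t$p_A, numeric(1))
  lp <- log(p[is.finite(p) & p > 0])
  if (length(lp) >= 2) {
    ts$population_median_log_p <- stats::median(lp)
    ts$population_mad_log_p <- 1.4826 * stats::mad(lp, constant = 1)
  } else {
    ts$population_median_log_p <- NA_real_
    ts$population_mad_log_p <- NA_real_
  }
  ts
}

#' @export
print.trace_set <- function(x, ...) {
  n <- length(x$traces)
  cat(sprintf("trace_set: %d helix trace%s\n", n, if (n == 1) "" else "s"))
  if (n) {
    L <- vapply(x$traces, `[[`, numeric(1), "L_A")
    p <- vapply(x$traces, `[[`, numeric(1), "p_A")
    cat(sprintf("  contour length: %.0f-%.0f A (median %.0f A)\n",
                min(L), max(L), stats::median(L)))
    fin <- is.finite(p) & p > 0
    if (any(fin))
      cat(sprintf("  persistence length: median %.3g um (%d finite)\n",
                  stats::median(p[fin]) / 1e4, sum(fin)))
  }
  invisible(x)
}

#' @export
summary.trace_set <- function(object, ...) {
  n <- length(object$traces)
  if (!n) { cat("empty trace_set\n"); return(invisible(object)) }
  L <- vapply(object$traces, `[[`, numeric(1), "L_A")
  R <- vapply(object$traces, `[[`, numeric(1), "R_A")
  p <- vapply(object$traces, `[[`, numeric(1), "p_A")
  print(object)
  cat("  R/L quartiles:", paste(signif(stats::quantile(R / L), 3),
                                collapse = " "), "\n")
  cat(sprintf("  ln(p) location %.3f, robust scale %.3f\n",
              object$population_median_log_p, object$population_mad_log_p))
  invisible(object)
}

#' @export
plot.trace_set <- function(x, add = FALSE, col = "red", ...) {
  if (!length(x$traces)) return(invisible(x))
  all_xy <- do.call(rbind, lapply(x$traces, `[[`, "coords_A"))
  if (!add)
    graphics::plot(NA, xlim = range(all_xy[, "x"]),
                   ylim = rev(range(all_xy[, "y"])), xlab = "x (A)",
                   ylab = "y (A)", asp = 1, ...)
  for (tr in x$traces)
    graphics::lines(tr$coords_A[, "x"], tr$coords_A[, "y"], col = col)
  invisible(x)
}

#' Prune over-bent traces from the population
#'
#' Persistence lengths across a helix population follow a log-normal
#' distribution; traces whose `ln(p)` lies more than `n_sigma` robust
#' standard deviations (median/MAD estimates) below the population median
#' are discarded, as are traces flagged maximally flexible. These are
#' typically kinked helices or elongated contamination rather than the
#' targeted assembly.
#'
#' @param ts a `trace_set`.
#' @param n_sigma robust-SD multiple (default 2).
#' @return pruned `trace_set` with statistics recomputed.
#' @export
prune_population <- function(ts, n_sigma = 2) {
  p <- vapply(ts$traces, function(t) t$p_A, numeric(1))
  defined <- is.finite(p) & p > 0
  if (sum(defined) < 5) {
    warning("fewer than 5 traces with defined persistence length; ",
            "pruning skipped")
    return(refresh_stats(ts))
  }
  lp <- log(p[defined])
  loc <- stats::median(lp)
  sc <- 1.4826 * stats::mad(lp, constant = 1)
  keep <- vapply(seq_along(ts$traces), function(i) {
    ti <- ts$traces[[i]]
    if (ti$flexible_flag || ti$p_A <= 0) return(FALSE)
    if (!is.finite(ti$p_A)) return(TRUE)  # rigid rods are never over-bent
    log(ti$p_A) >= loc - n_sigma * sc
  }, logical(1))
  ts$traces <- ts$traces[keep]
  refresh_stats(ts)
}
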