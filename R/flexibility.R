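# Ensemble flexibility: a discrete planar worm-like-chain simulator and the
# tangent-correlation persistence-length estimator. The operational model is
# <t(u) . t(u+s)> = exp(-s / p): successive tangent angles of the simulated
# chains take i.i.d. normal increments with variance 2 * segment / p, which
# makes the simulator and the estimator exact inverses in expectation.

#' Simulate a worm-like-chain ensemble
#'
#' Builds planar chains by an angular random walk: the tangent angle changes
#' between consecutive segments by independent normal increments of variance
#' `2 * segment_A / p_A`, giving an expected tangent correlation
#' `exp(-s / p_A)` at arc separation `s`. Chains start at the origin with a
#' uniformly random initial direction. `p_A = Inf` produces perfectly
#' straight chains.
#'
#' @param n_chains number of chains.
#' @param contour_A chain contour length in Angstrom.
#' @param segment_A segment length in Angstrom.
#' @param p_A generating persistence length in Angstrom (may be `Inf`).
#' @param seed integer RNG seed; the ensemble is reproducible bit-exactly.
#' @return object of class `wlc_ensemble`: list with `chains` (list of
#'   (n_seg+1) x 2 coordinate matrices in Angstrom), `segment_len_A`,
#'   `generating_p_A`, `seed`.
#' @export
simulate_wlc <- function(n_chains, contour_A, segment_A, p_A, seed = 1L) {
  stopifnot(n_chains >= 1, contour_A > 0, segment_A > 0,
            segment_A <= contour_A, p_A > 0)
  n_seg <- max(1L, round(contour_A / segment_A))
  sd_step <- if (is.finite(p_A)) sqrt(2 * segment_A / p_A) else 0
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  chains <- vector("list", n_chains)
  for (i in seq_len(n_chains)) {
    phi0 <- stats::runif(1, 0, 2 * pi)
    dphi <- if (sd_step > 0) stats::rnorm(n_seg - 1, 0, sd_step) else
      numeric(n_seg - 1)
    phi <- phi0 + c(0, cumsum(dphi))
    xy <- rbind(c(0, 0),
                cbind(cumsum(segment_A * cos(phi)),
                      cumsum(segment_A * sin(phi))))
    colnames(xy) <- c("x", "y")
    chains[[i]] <- xy
  }
  structure(list(chains = chains, segment_len_A = segment_A,
                 generating_p_A = p_A, seed = as.integer(seed)),
            class = "wlc_ensemble")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' @export
print.wlc_ensemble <- function(x, ...) {
  cat(sprintf(paste0("wlc_ensemble: %d chains, contour %.0f A, segment ",
                     "%.0f A, p = %.4g um (seed %d)\n"),
              length(x$chains),
              (nrow(x$chains[[1]]) - 1) * x$segment_len_A,
              x$segment_len_A, x$generating_p_A / 1e4, x$seed))
  invisible(x)
}

#' @export
plot.wlc_ensemble <- function(x, col = grDevices::adjustcolor("black", 0.3),
                              ...) {
  lim <- max(vapply(x$chains, function(ch) max(abs(ch)), numeric(1)))
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim),
                 xlab = "x (A)", ylab = "y (A)", asp = 1, ...)
  for (ch in x$chains) graphics::lines(ch[, 1], ch[, 2], col = col)
  invisible(x)
}

# coerce chain input: wlc_ensemble, trace_set, or plain list of matrices
chain_list <- function(chains) {
  if (inherits(chains, "wlc_ensemble")) return(chains$chains)
  if (inherits(chains, "trace_set"))
    return(lapply(chains$traces, `[[`, "coords_A"))
  chains
}

#' Mean tangent-vector correlation vs separation
#'
#' Computes unit tangents between consecutive segment coordinates and, for
#' each arc separation (multiples of the segment spacing), the mean dot
#' product between tangents that far apart, averaged over all chains and
#' positions.
#'
#' @param chains a `wlc_ensemble`, a `trace_set`, or a list of ordered
#'   coordinate matrices (Angstrom).
#' @param max_sep_A largest separation to evaluate.
#' @return object of class `tangent_correlation`: data.frame with
#'   `separation_A`, `mean_cos`, `n_pairs`, plus attribute `segment_A`.
#' @export
tangent_correlation <- function(chains, max_sep_A = NULL) {
  ch <- chain_list(chains)
  ch <- ch[vapply(ch, nrow, integer(1)) >= 3]
  if (!length(ch)) stop("need at least one chain with >= 3 points")
  seg <- mean(sqrt(rowSums(diff(ch[[1]])^2)))
  if (is.null(max_sep_A))
    max_sep_A <- max(vapply(ch, function(x) (nrow(x) - 2) * seg, numeric(1)))
  kmax <- max(1L, floor(max_sep_A / seg))
  sums <- numeric(kmax + 1L); counts <- numeric(kmax + 1L)
  for (x in ch) {
    tg <- diff(x)
    tg <- tg / sqrt(rowSums(tg^2))
    nt <- nrow(tg)
    for (k in 0:min(kmax, nt - 1L)) {
      dots <- rowSums(tg[seq_len(nt - k), , drop = FALSE] *
                      tg[seq_len(nt - k) + k, , drop = FALSE])
      sums[k + 1L] <- sums[k + 1L] + sum(dots)
      counts[k + 1L] <- counts[k + 1L] + length(dots)
    }
  }
  ok <- counts > 0
  structure(data.frame(separation_A = (0:kmax)[ok] * seg,
                       mean_cos = sums[ok] / counts[ok],
                       n_pairs = counts[ok]),
            segment_A = seg,
            class = c("tangent_correlation", "data.frame"))
}

#' Fit the persistence length to a tangent-correlation curve
#'
#' Least-squares fit of `exp(-s / p)` to the mean tangent correlations,
#' weighted by the number of contributing pairs. When all correlations are
#' positive the fit is performed on the linearized form `ln(c) = -s / p`
#' (through the origin, since `c(0) = 1` by construction); otherwise a 1-D
#' nonlinear least-squares search is used. Separations with fewer than 10
#' pairs are excluded. All-ones correlations return the rigid sentinel
#' `Inf`.
#'
#' @param tc a `tangent_correlation`.
#' @return persistence length in Angstrom (`Inf` for rigid input).
#' @export
fit_persistence <- function(tc) {
  d <- tc[tc$n_pairs >= 10, , drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 separations with enough pairs")
  if (all(d$mean_cos >= 1 - 1e-12)) return(Inf)
  s <- d$separation_A; cbar <- d$mean_cos; w <- d$n_pairs
  if (all(cbar > 0)) {
    slope <- sum(w * s * log(cbar)) / sum(w * s^2)
    if (slope >= 0) {
      warning("non-decaying tangent correlations; returning rigid sentinel")
      return(Inf)
    }
    return(-1 / slope)
  }
  # some non-positive correlations (very flexible or noisy): nonlinear fit
  sse <- function(logp) sum(w * (cbar - exp(-s / exp(logp)))^2)
  opt <- stats::optimize(sse, interval = log(c(max(s) * 1e-3, max(s) * 1e5)))
  exp(opt$minimum)
}
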