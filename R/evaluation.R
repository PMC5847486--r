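# Evaluation of tracing results against ground truth as a binary
# classification on coarse grids, plus the alpha/min-length grid search.

#' Rasterize traces onto a coarse evaluation grid
#'
#' Traces (Angstrom coordinates of the unbinned micrograph) are drawn onto a
#' blank binary grid of 25 A pixels: a cell is set when the helix path passes
#' through it. Optionally the grid is inflated (morphological dilation) by
#' the helix width, allowing for traces that do not sit exactly on the helix
#' axis. A 400 A margin around the micrograph boundary is excluded (the
#' periphery lacks usable signal), as are discs around trace endpoints
#' (radius two helix radii, read as one helix width) to remove the ambiguity
#' of where a tracer terminates a helix.
#'
#' @param traces a `trace_set` or list of coordinate matrices (`x`,`y` in A).
#' @param extent_A (width, height) of the micrograph in Angstrom.
#' @param helix_width_A helix width in Angstrom.
#' @param inflate dilate by the helix width.
#' @param grid_A grid pixel size (25 A).
#' @param margin_A boundary margin to clear (400 A).
#' @param extra_endpoints optional matrix of additional endpoint coordinates
#'   (Angstrom) whose exclusion discs are also cleared (used by
#'   [evaluate_traces()] to apply both sets' endpoints to both grids).
#' @param exclude_endpoints clear endpoint discs (default TRUE).
#' @return logical matrix (rows = y) of class `evaluation_grid`.
#' @export
traces_to_grid <- function(traces, extent_A, helix_width_A, inflate = FALSE,
                           grid_A = 25, margin_A = 400,
                           extra_endpoints = NULL, exclude_endpoints = TRUE) {
  coords <- chain_list(traces)
  nxc <- ceiling(extent_A[1] / grid_A)
  nyc <- ceiling(extent_A[2] / grid_A)
  g <- matrix(FALSE, nyc, nxc)
  endpoints <- NULL
  for (tr in coords) {
    if (is.null(tr) || nrow(tr) < 2) next
    # dense sampling of the polyline so no crossed cell is missed
    seg <- sqrt(rowSums(diff(tr)^2))
    n_dense <- pmax(2L, ceiling(seg / (grid_A / 5)))
    xs <- unlist(lapply(seq_along(seg), function(i)
      seq(tr[i, 1], tr[i + 1, 1], length.out = n_dense[i])))
    ys <- unlist(lapply(seq_along(seg), function(i)
      seq(tr[i, 2], tr[i + 1, 2], length.out = n_dense[i])))
    ix <- pmin(pmax(floor(xs / grid_A), 0), nxc - 1)
    iy <- pmin(pmax(floor(ys / grid_A), 0), nyc - 1)
    g[cbind(iy + 1, ix + 1)] <- TRUE
    endpoints <- rbind(endpoints, tr[1, 1:2], tr[nrow(tr), 1:2])
  }
  if (inflate && any(g)) {
    r <- round(helix_width_A / grid_A)
    if (r >= 1) {
      brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
      g <- EBImage::dilate(EBImage::Image(t(g)), brush)
      g <- t(EBImage::imageData(g)) > 0
    }
  }
  # boundary margin
  cx <- (seq_len(nxc) - 0.5) * grid_A
  cy <- (seq_len(nyc) - 0.5) * grid_A
  g[, cx < margin_A | cx > extent_A[1] - margin_A] <- FALSE
  g[cy < margin_A | cy > extent_A[2] - margin_A, ] <- FALSE
  # endpoint exclusion discs
  if (exclude_endpoints) {
    ep <- rbind(endpoints, extra_endpoints)
    if (!is.null(ep) && nrow(ep)) {
      r_ex <- helix_width_A  # two helix radii
      for (i in seq_len(nrow(ep))) {
        d2 <- outer((cy - ep[i, 2])^2, (cx - ep[i, 1])^2, "+")
        g[d2 <= r_ex^2] <- FALSE
      }
    }
  }
  structure(g, class = c("evaluation_grid", class(g)))
}

#' Harmonic mean of precision and recall
#' @param P,R precision and recall in `[0, 1]`.
#' @return F1 score; 0 when `P + R` is 0.
#' @export
f1_score <- function(P, R) ifelse(P + R > 0, 2 * P * R / (P + R), 0)

#' Score tracing results against ground truth
#'
#' Precision is the fraction of result grid points that coincide with the
#' helix-width-inflated ground-truth grid; recall is the fraction of
#' ground-truth grid points that coincide with the inflated result grid; F1
#' is their harmonic mean. Endpoint exclusion discs from both trace sets are
#' applied to both grids. An empty result scores 0/0/0 by convention.
#'
#' @param result_traces,truth_traces `trace_set`s or lists of coordinate
#'   matrices in Angstrom.
#' @param helix_width_A helix width in Angstrom.
#' @param extent_A (width, height) of the micrograph in Angstrom.
#' @param grid_A,margin_A grid pixel size and boundary margin.
#' @return object of class `evaluation_result`: list with `precision`,
#'   `recall`, `f1` and the coincidence counts.
#' @export
evaluate_traces <- function(result_traces, truth_traces, helix_width_A,
                            extent_A, grid_A = 25, margin_A = 400) {
  ends_of <- function(traces) {
    cs <- chain_list(traces)
    cs <- cs[vapply(cs, function(x) !is.null(x) && nrow(x) >= 2, logical(1))]
    if (!length(cs)) return(NULL)
    do.call(rbind, lapply(cs, function(x) x[c(1, nrow(x)), 1:2, drop = FALSE]))
  }
  ep_res <- ends_of(result_traces); ep_tru <- ends_of(truth_traces)
  mk <- function(traces, inflate, extra)
    traces_to_grid(traces, extent_A, helix_width_A, inflate = inflate,
                   grid_A = grid_A, margin_A = margin_A,
                   extra_endpoints = extra)
  g_res <- mk(result_traces, FALSE, ep_tru)
  g_tru <- mk(truth_traces, FALSE, ep_res)
  g_res_inf <- mk(result_traces, TRUE, ep_tru)
  g_tru_inf <- mk(truth_traces, TRUE, ep_res)
  n_res <- sum(g_res); n_tru <- sum(g_tru)
  n_correct <- sum(g_res & g_tru_inf)
  n_found <- sum(g_tru & g_res_inf)
  P <- if (n_res > 0) n_correct / n_res else 0
  R <- if (n_tru > 0) n_found / n_tru else 0
  structure(list(precision = P, recall = R, f1 = f1_score(P, R),
                 n_correct = n_correct, n_result = n_res,
                 n_found = n_found, n_truth = n_tru),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  F1 %.4f  (%d/%d result, %d/%d truth cells)\n",
              x$precision, x$recall, x$f1, x$n_correct, x$n_result,
              x$n_found, x$n_truth))
  invisible(x)
}

#' Grid search over alpha and minimum helix length
#'
#' Re-runs the (fast) extraction steps of precomputed correlation maps for
#' every combination of significance level and minimum-length cutoff and
#' scores the pooled result against ground truth. Returns the F1-maximizing
#' cell; ties resolve toward larger alpha, then smaller minimum length.
#'
#' @param contexts list of `trace_context` objects from [compute_cc_map()].
#' @param truths list of ground-truth trace sets (one per context; Angstrom
#'   coordinates).
#' @param alpha_grid significance levels to try (e.g. decades 1e-1..1e-6).
#' @param minlen_grid minimum helix lengths in Angstrom (e.g. 100 A steps).
#' @param prune apply population pruning before scoring.
#' @return list with `best_alpha`, `best_minlen`, `f1_matrix`,
#'   `precision_matrix`, `recall_matrix` (rows = min length, cols = alpha).
#' @export
grid_search <- function(contexts, truths, alpha_grid, minlen_grid,
                        prune = TRUE) {
  stopifnot(length(contexts) == length(truths),
            length(alpha_grid) > 0, length(minlen_grid) > 0)
  f1m <- pm <- rm <- matrix(NA_real_, length(minlen_grid), length(alpha_grid),
                            dimnames = list(minlen_grid, alpha_grid))
  for (ia in seq_along(alpha_grid)) for (il in seq_along(minlen_grid)) {
    tot_correct <- tot_res <- tot_found <- tot_tru <- 0
    results <- lapply(contexts, extract_traces, alpha = alpha_grid[ia],
                      min_len_A = minlen_grid[il])
    if (prune) {
      pooled <- trace_set(unlist(lapply(results, `[[`, "traces"),
                                 recursive = FALSE))
      pooled <- suppressWarnings(
        prune_population(pooled, contexts[[1]]$params$prune_n_sigma))
      ids <- vapply(pooled$traces, `[[`, character(1), "micrograph_id")
      results <- lapply(seq_along(contexts), function(i)
        trace_set(pooled$traces[ids == contexts[[i]]$id]))
    }
    for (i in seq_along(contexts)) {
      ev <- evaluate_traces(results[[i]], truths[[i]],
                            contexts[[i]]$params$helix_width_A,
                            contexts[[i]]$extent_A)
      tot_correct <- tot_correct + ev$n_correct
      tot_res <- tot_res + ev$n_result
      tot_found <- tot_found + ev$n_found
      tot_tru <- tot_tru + ev$n_truth
    }
    P <- if (tot_res > 0) tot_correct / tot_res else 0
    R <- if (tot_tru > 0) tot_found / tot_tru else 0
    pm[il, ia] <- P; rm[il, ia] <- R; f1m[il, ia] <- f1_score(P, R)
  }
  # argmax with ties toward larger alpha, then smaller min length
  best <- which(f1m == max(f1m), arr.ind = TRUE)
  best <- best[order(-alpha_grid[best[, 2]], minlen_grid[best[, 1]]), ,
               drop = FALSE][1, ]
  list(best_alpha = alpha_grid[best[2]], best_minlen = minlen_grid[best[1]],
       f1_matrix = f1m, precision_matrix = pm, recall_matrix = rm)
}
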