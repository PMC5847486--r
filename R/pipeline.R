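# Pipeline driver: preprocessing + tile matching + map accumulation are the
# slow stages and are computed once per micrograph (compute_cc_map); the
# extraction stages (thresholding through trace fitting) are fast and can be
# re-run cheaply, e.g. inside the parameter grid search.

#' Compute the correlation map for a micrograph (slow stage)
#'
#' Bins and normalizes the micrograph, applies the Gaussian high-pass and
#' dark-outlier suppression, matches every tile against the reference and
#' accumulates the matches into a continuous correlation map.
#'
#' @param m a [micrograph()] (raw, unbinned).
#' @param ref a [reference_helix()].
#' @param params [tracing_params()].
#' @return object of class `trace_context`: list with the binned micrograph,
#'   tile grid, matches, correlation map, fitted null, working pixel size,
#'   micrograph extent (A) and the parameters.
#' @export
compute_cc_map <- function(m, ref, params) {
  extent_A <- c(ncol(m$pixels), nrow(m$pixels)) * m$pixel_size_A
  work <- normalize_and_bin(m, params$binning_factor)
  work <- highpass(work)
  work <- suppress_outliers(work)
  grid <- make_tile_grid(dim(work$pixels), params, work$pixel_size_A)
  pref <- prepare_reference(ref, grid, work$pixel_size_A)
  matches <- match_all_tiles(work, grid, pref, params)
  map <- accumulate_map(matches, grid, dim(work$pixels))
  null <- tryCatch(fit_null(map), error = function(e) NULL)
  structure(list(id = m$source_id, micrograph = work, grid = grid,
                 reference = pref, matches = matches, map = map,
                 null = null, pixel_size_A = work$pixel_size_A,
                 extent_A = extent_A, params = params),
            class = "trace_context")
}

#' Extract helix traces from a correlation map (fast stage)
#'
#' Thresholds the correlation map against its exponential null, skeletonizes
#' the binary map, erases branch-point regions to split crossing helices,
#' orders the remaining components into pixel paths, filters/splits them by
#' length, and fits each to a polynomial trace with equidistant segment
#' coordinates. Coordinates are returned in Angstrom of the unbinned
#' micrograph (0-based pixel origin).
#'
#' @param ctx a `trace_context` from [compute_cc_map()].
#' @param alpha significance level (default from the context's params).
#' @param min_len_A,max_len_A length window (defaults from params).
#' @return a [trace_set()] (unpruned).
#' @export
extract_traces <- function(ctx, alpha = NULL, min_len_A = NULL,
                           max_len_A = NULL) {
  p <- ctx$params
  if (is.null(alpha)) alpha <- p$alpha
  if (is.null(min_len_A)) min_len_A <- p$min_helix_len_A
  if (is.null(max_len_A)) max_len_A <- p$max_helix_len_A
  if (is.null(ctx$null)) return(trace_set())
  binary <- threshold_map(ctx$map, ctx$null, alpha)
  if (!any(binary)) return(trace_set())
  skel <- skeletonize(binary)
  bp <- detect_branch_points(skel)
  skel <- erase_branch_regions(skel, bp, p$helix_width_A, ctx$pixel_size_A)
  paths <- extract_paths(skel)
  paths <- filter_and_split(paths, min_len_A, max_len_A, ctx$pixel_size_A)
  traces <- lapply(paths, function(pt)
    tryCatch(fit_trace(pt, ctx$pixel_size_A,
                       segment_spacing_A = p$segment_spacing_A,
                       micrograph_id = ctx$id),
             error = function(e) NULL))
  trace_set(Filter(Negate(is.null), traces))
}

#' Trace all helices in a micrograph
#'
#' Runs the full pipeline -- preprocessing, tile matching, map accumulation,
#' thresholding, skeletonization, branch splitting, length filtering,
#' polynomial fitting and (optionally) population pruning -- and returns the
#' final trace set in Angstrom coordinates of the unbinned micrograph.
#' Deterministic for fixed inputs.
#'
#' @param m a [micrograph()].
#' @param ref a [reference_helix()].
#' @param params [tracing_params()].
#' @param prune apply persistence-length population pruning.
#' @return a [trace_set()].
#' @export
trace_micrograph <- function(m, ref, params, prune = TRUE) {
  ctx <- compute_cc_map(m, ref, params)
  ts <- extract_traces(ctx)
  if (prune && length(ts$traces))
    ts <- suppressWarnings(prune_population(ts, params$prune_n_sigma))
  ts
}

# ---- coordinate file I/O ---------------------------------------------------

#' Write traces as an EMAN-style helix box file
#'
#' One line per helix start and end coordinate: `x y box box flag`, where
#' `x`/`y` are unbinned pixel coordinates of the box corner (center minus
#' half the box size), and the flag is -1 for a helix start and -2 for its
#' end. With `segments = TRUE` every equidistant segment coordinate is
#' written (intermediate flag 0), which is also readable as a generic
#' coordinate table by RELION-style importers.
#'
#' @param ts a `trace_set`.
#' @param path output file path.
#' @param pixel_size_A pixel size of the unbinned micrograph (A/px).
#' @param box_size_px box edge length in unbinned pixels.
#' @param segments write every segment coordinate, not only start/end.
#' @export
write_box <- function(ts, path, pixel_size_A, box_size_px = 100,
                      segments = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# helix box coordinates (px, corner convention, box %d)",
                     box_size_px), con)
  for (tr in ts$traces) {
    co <- tr$coords_A / pixel_size_A - box_size_px / 2
    rows <- if (segments) seq_len(nrow(co)) else c(1L, nrow(co))
    flags <- rep(0L, length(rows))
    flags[1] <- -1L; flags[length(flags)] <- -2L
    for (j in seq_along(rows))
      writeLines(sprintf("%d\t%d\t%d\t%d\t%d",
                         round(co[rows[j], 1]), round(co[rows[j], 2]),
                         box_size_px, box_size_px, flags[j]), con)
  }
  invisible(path)
}

#' Read an EMAN-style helix box file
#'
#' @param path box file written by [write_box()] (or compatible).
#' @param pixel_size_A pixel size of the unbinned micrograph (A/px).
#' @return list of coordinate matrices (`x`,`y` in Angstrom), one per helix.
#' @export
read_box <- function(path, pixel_size_A) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(list())
  tab <- utils::read.table(text = lines)
  traces <- list()
  cur <- NULL
  for (i in seq_len(nrow(tab))) {
    ctr <- (as.numeric(tab[i, 1:2]) + as.numeric(tab[i, 3:4]) / 2) *
      pixel_size_A
    cur <- rbind(cur, ctr)
    if (tab[i, 5] == -2) {
      colnames(cur) <- c("x", "y"); rownames(cur) <- NULL
      traces[[length(traces) + 1]] <- cur
      cur <- NULL
    }
  }
  traces
}

#' Read a key = value tracing config file
#'
#' Lines of the form `key = value`; keys are matched (case- and
#' separator-insensitively) against the [tracing_params()] argument names,
#' e.g. `tile_size_A = 500`, `alpha = 0.000859`.
#'
#' @param path config file path.
#' @return a [tracing_params()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.+?)\\s*$", lines))
  args <- list()
  norm <- function(s) gsub("[^a-z0-9]", "", tolower(s))
  formals_names <- names(formals(tracing_params))
  for (m in kv) {
    if (length(m) != 3) next
    hit <- formals_names[norm(formals_names) == norm(m[2])]
    if (length(hit) == 1) args[[hit]] <- as.numeric(m[3])
  }
  do.call(tracing_params, args)
}
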