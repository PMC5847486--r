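#' Construct a micrograph object
#'
#' A micrograph is a 2-D gray-scale pixel array together with its pixel size
#' in Angstrom. Pixels are stored as a numeric matrix with rows = y (down)
#' and columns = x (right); all coordinates in the package are 0-based pixel
#' indices with the origin at the top-left corner, so that Angstrom
#' coordinates are `pixel index * pixel_size_A`.
#'
#' @param pixels numeric matrix of pixel values.
#' @param pixel_size_A pixel size in Angstrom per pixel (> 0).
#' @param source_id text label identifying the image (file name or synthetic
#'   scene id).
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size_A, source_id = "unknown") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) stop("micrograph pixels must all be finite")
  if (!is.numeric(pixel_size_A) || length(pixel_size_A) != 1 ||
      !is.finite(pixel_size_A) || pixel_size_A <= 0)
    stop("pixel_size_A must be a single positive number")
  structure(list(pixels = pixels, pixel_size_A = as.numeric(pixel_size_A),
                 source_id = as.character(source_id)),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("micrograph '%s': %d x %d px at %.4g A/px (%.0f x %.0f A)\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels), x$pixel_size_A,
              ncol(x$pixels) * x$pixel_size_A, nrow(x$pixels) * x$pixel_size_A))
  cat(sprintf("  intensity: mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
              mean(x$pixels), stats::sd(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

#' @export
plot.micrograph <- function(x, ...) {
  px <- x$pixels
  rng <- range(px)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  # flip rows so the image displays with the origin at the top-left
  graphics::image(t(px[nrow(px):1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1), zlim = rng,
                  axes = FALSE, asp = nrow(px) / ncol(px), ...)
  invisible(x)
}

# ---- MRC2014 I/O -----------------------------------------------------------
# Minimal reader/writer for single-image MRC2014 files, modes 0 (int8),
# 1 (int16) and 2 (float32). Data are stored x-fastest; the pixel size is
# cella/mx from the header.

#' Read a 2-D MRC image
#'
#' @param path path to an MRC2014 file (mode 0, 1 or 2, single section).
#' @return list with `pixels` (matrix, rows = y), `pixel_size_A` (NA when the
#'   header carries no cell information) and header fields `nx`, `ny`, `mode`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  if (any(c(nx, ny, nz) <= 0) || nx > 1e6 || ny > 1e6)
    stop("not a readable MRC file: ", path)
  if (nz != 1)
    stop("unsupported dimensionality: MRC stack with nz = ", nz,
         " (only single 2-D images are supported)")
  if (!mode %in% c(0L, 1L, 2L))
    stop("unsupported MRC mode ", mode, " (modes 0/1/2 supported)")
  mxyz <- hdr_int[8:10]
  cella <- readBin(con, "double", n = 3, size = 4, endian = "little")
  pixel_size <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else NA_real_
  seek(con, 1024)
  n <- nx * ny
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "double", n = n, size = 4, endian = "little"))
  if (length(vals) != n) stop("truncated MRC data in ", path)
  # x varies fastest on disk -> matrix(nrow = nx) has pixels[x, y]; transpose
  pixels <- t(matrix(vals, nrow = nx, ncol = ny))
  list(pixels = pixels, pixel_size_A = pixel_size, nx = nx, ny = ny, mode = mode)
}

#' Write a 2-D image as MRC2014 (mode 2, float32)
#'
#' @param pixels numeric matrix (rows = y).
#' @param path output path.
#' @param pixel_size_A pixel size in Angstrom recorded in the header cell.
#' @export
write_mrc <- function(pixels, path, pixel_size_A = 1) {
  pixels <- as.matrix(pixels)
  ny <- nrow(pixels); nx <- ncol(pixels)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, 1, 2))            # nx ny nz mode
  wi(c(0, 0, 0))                 # nxstart nystart nzstart
  wi(c(nx, ny, 1))               # mx my mz
  wf(c(nx, ny, 1) * pixel_size_A)  # cella
  wf(c(90, 90, 90))              # cellb
  wi(c(1, 2, 3))                 # mapc mapr maps
  wf(c(min(pixels), max(pixels), mean(pixels)))  # dmin dmax dmean
  wi(c(0, 0))                    # ispg nsymbt
  wi(rep(0L, 25))                # extra
  wf(c(0, 0, 0))                 # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(as.numeric(pixels)))                 # rms
  wi(0)                          # nlabl
  writeBin(raw(800), con)        # labels
  wf(as.numeric(t(pixels)))      # data, x fastest
  invisible(path)
}

#' Load a micrograph from disk
#'
#' Reads MRC2014 (preferred) or 8/16-bit gray-scale PNG. For MRC the pixel
#' size is taken from the header when present, otherwise from `pixel_size_A`.
#'
#' @param path path to an MRC or PNG file.
#' @param pixel_size_A fallback pixel size in Angstrom when the file header
#'   carries none (always needed for PNG).
#' @return A [micrograph()].
#' @export
load_micrograph <- function(path, pixel_size_A = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) px <- px[, , 1]  # first channel of RGB(A)
    if (is.null(pixel_size_A))
      stop("pixel_size_A is required for PNG input")
    return(micrograph(px, pixel_size_A, source_id = basename(path)))
  }
  m <- read_mrc(path)
  ps <- m$pixel_size_A
  if (is.na(ps)) {
    if (is.null(pixel_size_A))
      stop("MRC header has no pixel size; supply pixel_size_A")
    ps <- pixel_size_A
  }
  micrograph(m$pixels, ps, source_id = basename(path))
}
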