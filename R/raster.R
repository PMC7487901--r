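#' Raster: a 2-D grayscale intensity image with physical pixel size
#'
#' The universal image currency of the package. Pixels are stored as a numeric
#' matrix in (row, col) order, 0-based physical convention: physical
#' x = (col - 1) * pixel_size_um, y = (row - 1) * pixel_size_um. Intensities
#' are held as doubles internally regardless of the source bit depth; the
#' source depth is kept only so integer writing can round-trip losslessly.
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param pixel_size_um physical size of one pixel in micrometers (> 0). The
#'   assays this package supports never state a calibration in their raw
#'   files, so the default is 1 with a one-time warning.
#' @param bit_depth source bit depth: 8, 16, or 32 (32 = IEEE float).
#' @return an object of class `raster_img`.
#' @export
raster_img <- function(pixels, pixel_size_um = NULL, bit_depth = 16L) {
  if (is.vector(pixels)) pixels <- matrix(pixels, nrow = 1L)
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1L, ncol(pixels) >= 1L)
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("raster intensities must all be finite")
  if (any(pixels < 0)) stop("raster intensities must be >= 0")
  if (is.null(pixel_size_um)) {
    warning("pixel_size_um not supplied; assuming 1 um/px", call. = FALSE)
    pixel_size_um <- 1
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (!bit_depth %in% c(8L, 16L, 32L)) stop("bit_depth must be 8, 16 or 32")
  structure(list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
                 bit_depth = as.integer(bit_depth)),
            class = "raster_img")
}

#' @export
print.raster_img <- function(x, ...) {
  cat(sprintf("<raster_img> %d x %d px, %.4g um/px, %d-bit, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.raster_img <- function(x) dim(x$pixels)

#' Binary cell mask aligned to a raster
#'
#' Convention: 1 = inside the cell (foreground), 0 = background.
#'
#' @param pixels matrix of 0/1 (logical or numeric) values.
#' @return an object of class `cell_mask` whose `pixels` are integer 0/1.
#' @export
cell_mask <- function(pixels) {
  if (inherits(pixels, "cell_mask")) return(pixels)
  stopifnot(is.matrix(pixels))
  m <- matrix(as.integer(pixels != 0), nrow(pixels), ncol(pixels))
  if (anyNA(m)) stop("mask values must be 0/1")
  structure(list(pixels = m), class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d x %d px, %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' @export
dim.cell_mask <- function(x) dim(x$pixels)

# Accept raster_img / cell_mask / bare matrix interchangeably in internal code.
.px <- function(x) {
  if (inherits(x, c("raster_img", "cell_mask"))) x$pixels else x
}

.mask_logical <- function(x, dims = NULL) {
  m <- .px(x) != 0
  if (!is.null(dims) && !identical(dim(m), as.integer(dims)))
    stop("mask shape does not match raster shape")
  m
}

.pixel_size <- function(x, default = 1) {
  if (inherits(x, "raster_img")) x$pixel_size_um else default
}
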