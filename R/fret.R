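# Ratiometric FRET biosensor quantification.
#
# Activation of a GTPase biosensor is read out as the per-pixel ratio of the
# sensitized-emission FRET channel (CFP excitation / YFP emission) to the
# donor channel (CFP excitation / CFP emission), restricted to a cell mask
# derived from the directly-excited acceptor (YFP) image, after background
# correction of both channels. Per-cell activation is the arithmetic mean of
# the defined ratio pixels; conditions are compared as fold change of mean
# ratios relative to a control group.

#' Bundle the three channels of a FRET acquisition
#'
#' @param donor donor channel (CFP exc / CFP em) [raster_img()].
#' @param fret sensitized-emission channel (CFP exc / YFP em).
#' @param acceptor acceptor channel (YFP exc / YFP em), used for masking.
#' @return a `fret_image_set`.
#' @export
fret_image_set <- function(donor, fret, acceptor) {
  imgs <- list(donor = donor, fret = fret, acceptor = acceptor)
  stopifnot(all(vapply(imgs, inherits, logical(1), "raster_img")))
  d <- dim(donor$pixels)
  if (!identical(d, dim(fret$pixels)) || !identical(d, dim(acceptor$pixels)))
    stop("donor, fret and acceptor rasters must share one shape")
  ps <- vapply(imgs, function(r) r$pixel_size_um, numeric(1))
  if (diff(range(ps)) > 0) stop("channel pixel sizes differ")
  structure(imgs, class = "fret_image_set")
}

#' @export
print.fret_image_set <- function(x, ...) {
  cat(sprintf("<fret_image_set> %d x %d px, %.4g um/px\n",
              nrow(x$donor$pixels), ncol(x$donor$pixels),
              x$donor$pixel_size_um))
  invisible(x)
}

#' Background-correct a raster
#'
#' Subtracts the median intensity of a background (non-cell) region and
#' clips at zero. When no region is supplied, one is derived automatically
#' as the complement of the dilated thresholded foreground.
#'
#' @param raster a [raster_img()] (or matrix).
#' @param background_region optional [cell_mask()] of background pixels.
#' @param dilation_px safety dilation of the auto-derived foreground before
#'   taking its complement.
#' @return a background-corrected [raster_img()].
#' @export
correct_background <- function(raster, background_region = NULL,
                               dilation_px = 5L) {
  px <- .px(raster)
  if (is.null(background_region)) {
    fg <- px > .otsu(as.vector(px))
    bg <- !.dilate_disk(fg, dilation_px)
    if (!any(bg)) stop("auto background region is empty")
  } else {
    bg <- .mask_logical(background_region, dim(px))
    if (!any(bg)) stop("background region is empty")
  }
  out <- pmax(px - stats::median(px[bg]), 0)
  raster_img(out, .pixel_size(raster), bit_depth = 32L)
}

#' Segment the cell from the acceptor (YFP) image
#'
#' Thresholds the acceptor image, fills holes, and keeps the largest
#' 8-connected component, yielding a binary mask with 1 inside the cell.
#'
#' @param acceptor acceptor [raster_img()] (or matrix).
#' @param method thresholding method; only `"otsu"` is provided.
#' @param min_area_px smallest acceptable cell area.
#' @return a [cell_mask()].
#' @export
make_cell_mask <- function(acceptor, method = c("otsu"), min_area_px = 64L) {
  method <- match.arg(method)
  px <- .px(acceptor)
  if (diff(range(px)) == 0)
    stop("acceptor image is uniform; no cell to segment (empty mask)")
  fg <- px > .otsu(as.vector(px))
  if (!any(fg)) stop("threshold produced an empty mask")
  fg <- .fill_holes(fg)
  lab <- .label_components(fg)
  sizes <- tabulate(lab[lab > 0])
  if (max(sizes) < min_area_px)
    stop("no connected component reaches min_area_px (empty mask)")
  cell_mask(lab == which.max(sizes))
}

#' Per-cell FRET/donor ratio image
#'
#' Divides the background-corrected FRET channel by the donor channel over
#' the mask. Pixels whose donor intensity does not exceed `donor_floor` are
#' removed from the mask before division (dim pixels make the ratio
#' explode); the floor defaults to 3x a robust estimate of the background
#' noise sd taken from donor pixels outside the mask.
#'
#' @param set a [fret_image_set()], background-corrected.
#' @param mask a [cell_mask()] (e.g. from [make_cell_mask()]).
#' @param donor_floor minimum donor intensity for a pixel to count; `NULL`
#'   for the automatic 3-sigma floor.
#' @return a `ratio_image`: `pixels` (ratio, `NA` off-mask), the effective
#'   `mask`, `mean_ratio` (arithmetic mean of defined pixel ratios — the
#'   default per-cell summary), `ratio_of_means` (alternative estimator:
#'   mean FRET / mean donor), `n_px`.
#' @export
ratio_image <- function(set, mask, donor_floor = NULL) {
  stopifnot(inherits(set, "fret_image_set"))
  d <- .px(set$donor); f <- .px(set$fret)
  m <- .mask_logical(mask, dim(d))
  if (!any(m)) stop("mask is empty")
  if (is.null(donor_floor)) {
    out_px <- d[!m]
    donor_floor <- if (length(out_px)) 3 * stats::mad(out_px) else 0
  }
  keep <- m & d > donor_floor
  if (!any(keep)) stop("all pixels fail the donor floor")
  ratio <- matrix(NA_real_, nrow(d), ncol(d))
  ratio[keep] <- f[keep] / d[keep]
  structure(list(pixels = ratio, mask = cell_mask(keep),
                 mean_ratio = mean(ratio[keep]),
                 ratio_of_means = mean(f[keep]) / mean(d[keep]),
                 n_px = sum(keep), donor_floor = donor_floor),
            class = "ratio_image")
}

#' @export
print.ratio_image <- function(x, ...) {
  cat(sprintf("<ratio_image> %d px in mask, mean ratio %.4f\n",
              x$n_px, x$mean_ratio))
  invisible(x)
}

#' Fold change of mean FRET ratios versus control
#'
#' `mean(sample cell means) / mean(control cell means)`: the per-condition
#' summary used to report biosensor activation relative to control cells.
#'
#' @param sample_means per-cell mean ratios in the sample condition.
#' @param control_means per-cell mean ratios in the control condition.
#' @return the fold change (scalar).
#' @export
fret_fold_change <- function(sample_means, control_means) {
  if (!length(sample_means) || !length(control_means))
    stop("both conditions need at least one cell")
  ctrl <- mean(control_means)
  if (!is.finite(ctrl) || ctrl <= 0) stop("control mean ratio must be > 0")
  mean(sample_means) / ctrl
}
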