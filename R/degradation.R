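# Fluorescent-gelatin matrix degradation index.
#
# Cells that form functional invadopodia digest the labelled gelatin under
# their footprint, so the matrix under a degrading cell is dimmer than the
# intact matrix nearby. The per-cell index D divides the mean matrix
# fluorescence in an equal-area background region of interest adjacent to
# the cell by the mean under the cell trace; D > 1 reflects degradation and
# D = 1 means an untouched matrix.

#' Trace a cell footprint from a DIC-proxy or GFP channel
#'
#' Same segmentation contract as [make_cell_mask()]: threshold, fill holes,
#' keep the largest component. A manually supplied [cell_mask()] passes
#' through unchanged.
#'
#' @param cells a cell-channel [raster_img()]/matrix aligned to the matrix
#'   image, or an existing [cell_mask()].
#' @param min_area_px smallest acceptable footprint.
#' @return a [cell_mask()].
#' @export
trace_cell <- function(cells, min_area_px = 64L) {
  if (inherits(cells, "cell_mask")) return(cells)
  make_cell_mask(cells, min_area_px = min_area_px)
}

#' Equal-area background region of interest next to a cell
#'
#' Grows an annulus outward from the cell footprint ring by ring (excluding
#' every cell footprint in the field) until it holds exactly as many pixels
#' as the cell trace - the "similar ROI in the background" convention. The
#' nominal `dilation_px` sets where growth starts looking; growth continues
#' past it if the immediate surroundings cannot supply enough area.
#'
#' @param cell_mask the cell's [cell_mask()].
#' @param all_cells_mask mask of every cell footprint in the field (defaults
#'   to `cell_mask` when the cell is alone).
#' @param dilation_px nominal annulus extent, px.
#' @return a background [cell_mask()] with exactly the cell's area (errors
#'   if less than 25% of that area is available).
#' @export
background_roi <- function(cell_mask, all_cells_mask = cell_mask,
                           dilation_px = 10L) {
  cm <- .mask_logical(cell_mask)
  if (!any(cm)) stop("cell mask is empty")
  allm <- .mask_logical(all_cells_mask, dim(cm))
  target <- sum(cm)
  roi <- matrix(FALSE, nrow(cm), ncol(cm))
  prev <- cm
  r <- 0L
  max_r <- max(dim(cm))
  grow1 <- function(m) {  # one 8-connected dilation step
    out <- m
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      out <- out | .shift_mat(m, dr, dc, FALSE)
    }
    out
  }
  while (sum(roi) < target && r < max_r) {
    r <- r + 1L
    cur <- grow1(prev)
    ring <- cur & !prev & !allm
    prev <- cur
    avail <- which(ring)
    need <- target - sum(roi)
    if (length(avail) > need) avail <- avail[seq_len(need)]  # row-major trim
    roi[avail] <- TRUE
  }
  if (sum(roi) < 0.25 * target)
    stop("insufficient background around the cell for an equal-area ROI")
  cell_mask(roi)
}

#' Per-cell matrix degradation index
#'
#' `D = mean(matrix over background ROI) / mean(matrix under the cell
#' trace)`. A fully degraded footprint (cell mean at or below `eps` times
#' the background mean) is reported as `D = Inf` with a flag rather than an
#' error.
#'
#' @param matrix_img the labelled-matrix [raster_img()]/matrix.
#' @param cell_mask footprint [cell_mask()] from [trace_cell()].
#' @param bg_roi background [cell_mask()] from [background_roi()].
#' @param cell_id identifier carried into the result.
#' @param eps relative floor under which the cell mean counts as zero.
#' @return a one-row data.frame: `cell_id`, `cell_mean`, `bg_mean`, `index`,
#'   `fully_degraded`.
#' @export
degradation_index <- function(matrix_img, cell_mask, bg_roi, cell_id = 1L,
                              eps = 1e-6) {
  px <- .px(matrix_img)
  cm <- .mask_logical(cell_mask, dim(px))
  bm <- .mask_logical(bg_roi, dim(px))
  if (!any(cm) || !any(bm)) stop("cell mask and background ROI must be non-empty")
  if (any(cm & bm)) stop("cell mask and background ROI overlap")
  cell_mean <- mean(px[cm]); bg_mean <- mean(px[bm])
  fully <- cell_mean <= eps * max(bg_mean, .Machine$double.eps)
  data.frame(cell_id = cell_id, cell_mean = cell_mean, bg_mean = bg_mean,
             index = if (fully) Inf else bg_mean / cell_mean,
             fully_degraded = fully)
}

#' Degradation fold change versus control
#'
#' Mean sample index over mean control index; infinite (fully-degraded)
#' sentinels are excluded with a warning.
#'
#' @param sample_d,control_d numeric vectors of per-cell indices D.
#' @return fold change (scalar).
#' @export
degradation_fold <- function(sample_d, control_d) {
  drop_inf <- function(v, who) {
    bad <- !is.finite(v)
    if (any(bad))
      warning(sum(bad), " non-finite ", who,
              " degradation indices excluded from the fold change")
    v[!bad]
  }
  s <- drop_inf(sample_d, "sample"); ctl <- drop_inf(control_d, "control")
  if (!length(ctl)) stop("control has no finite degradation indices")
  if (!length(s)) stop("sample has no finite degradation indices")
  mean(s) / mean(ctl)
}
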