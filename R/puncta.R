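# Punctate-structure detection and scoring.
#
# Focal adhesions (vinculin) and invadopodia (TKS4) are detected the way the
# classic ImageJ recipe does it: local contrast enhancement (CLAHE) followed
# by Laplacian-of-Gaussian blob filtering, robust thresholding of the
# response, and connected-component analysis. Adhesion size is summarized as
# fold difference to control; invadopodia as absolute counts per cell.

#' Contrast-limited adaptive histogram equalization
#'
#' Classic CLAHE: the image is divided into tiles, each tile's histogram is
#' clipped at `clip_limit` (as a fraction of the tile's pixel count, excess
#' redistributed uniformly) and turned into an equalization mapping; pixel
#' values are bilinearly interpolated between the four neighbouring tile
#' mappings. Output lies in [0, 1].
#'
#' @param raster a [raster_img()] or matrix.
#' @param tile_px tile edge length in px (>= 8, <= image size).
#' @param clip_limit histogram clip limit as a fraction of tile pixels,
#'   in (0, 1].
#' @param nbins histogram bins.
#' @return a matrix in [0, 1] with the input's shape.
#' @export
clahe <- function(raster, tile_px = 64L, clip_limit = 0.01, nbins = 256L) {
  px <- .px(raster)
  nr <- nrow(px); nc <- ncol(px)
  if (tile_px < 8L) stop("tile_px must be >= 8")
  if (tile_px > nr || tile_px > nc) stop("tile larger than image")
  if (clip_limit <= 0 || clip_limit > 1) stop("clip_limit must be in (0, 1]")
  rng <- range(px)
  if (diff(rng) == 0) return(matrix(0.5, nr, nc))
  v <- (px - rng[1]) / diff(rng)
  bin <- pmin(nbins, 1L + floor(v * nbins))
  ntr <- ceiling(nr / tile_px); ntc <- ceiling(nc / tile_px)
  tr <- pmin(ntr, 1L + (seq_len(nr) - 1L) %/% tile_px)
  tc <- pmin(ntc, 1L + (seq_len(nc) - 1L) %/% tile_px)
  tile_id <- matrix(tr, nr, nc) + (matrix(tc, nr, nc, byrow = TRUE) - 1L) * ntr
  n_tiles <- ntr * ntc
  H <- matrix(tabulate((tile_id - 1L) * nbins + bin, nbins * n_tiles),
              nrow = n_tiles, byrow = TRUE)
  npix <- tabulate(tile_id, n_tiles)
  M <- matrix(0, n_tiles, nbins)
  for (t in seq_len(n_tiles)) {
    h <- H[t, ]
    cl <- max(1, clip_limit * npix[t])
    excess <- sum(pmax(h - cl, 0))
    h <- pmin(h, cl) + excess / nbins
    M[t, ] <- cumsum(h) / sum(h)
  }
  # tile centres along each axis (last tile may be partial)
  ctr <- function(n, nt) {
    starts <- (seq_len(nt) - 1L) * tile_px + 1L
    ends <- pmin(starts + tile_px - 1L, n)
    (starts + ends) / 2
  }
  cr <- ctr(nr, ntr); cc <- ctr(nc, ntc)
  brack <- function(pos, centers) {
    nt <- length(centers)
    if (nt == 1L) return(list(i0 = rep(1L, length(pos)),
                              i1 = rep(1L, length(pos)),
                              w = rep(0, length(pos))))
    i0 <- pmin(pmax(findInterval(pos, centers), 1L), nt - 1L)
    w <- (pos - centers[i0]) / (centers[i0 + 1L] - centers[i0])
    list(i0 = i0, i1 = i0 + 1L, w = pmin(pmax(w, 0), 1))
  }
  br <- brack(seq_len(nr), cr); bc <- brack(seq_len(nc), cc)
  R0 <- matrix(br$i0, nr, nc); R1 <- matrix(br$i1, nr, nc)
  WR <- matrix(br$w, nr, nc)
  C0 <- matrix(bc$i0, nr, nc, byrow = TRUE); C1 <- matrix(bc$i1, nr, nc, byrow = TRUE)
  WC <- matrix(bc$w, nr, nc, byrow = TRUE)
  look <- function(R, C) matrix(M[cbind(as.vector(R + (C - 1L) * ntr),
                                        as.vector(bin))], nr, nc)
  out <- (1 - WR) * (1 - WC) * look(R0, C0) + WR * (1 - WC) * look(R1, C0) +
    (1 - WR) * WC * look(R0, C1) + WR * WC * look(R1, C1)
  pmin(pmax(out, 0), 1)
}

#' Scale-normalized Laplacian-of-Gaussian blob response
#'
#' Returns `-sigma^2 * Laplacian(Gaussian(sigma) * image)`, so bright blobs
#' give positive peaks at their centres; the response to a Gaussian spot of
#' nominal radius r peaks over scales at `sigma ~ r / sqrt(2)`. Constant
#' images and linear ramps map to (numerically) zero away from borders.
#'
#' @param raster a [raster_img()] or matrix.
#' @param sigma_px filter scale in px (>= 0.5).
#' @return response matrix with the input's shape.
#' @export
log_response <- function(raster, sigma_px) {
  if (sigma_px < 0.5) stop("sigma_px must be >= 0.5")
  .log_filter(.px(raster), sigma_px)
}

#' Construct a set of detected puncta
#'
#' @param puncta data.frame with (at least) columns `id`, `row`, `col`,
#'   `area_px`, `area_um2`, `mean_int`.
#' @param mask optional parent-cell [cell_mask()].
#' @param params detection parameters used, kept for provenance.
#' @return a `puncta_set`.
#' @export
puncta_set <- function(puncta, mask = NULL, params = list()) {
  structure(list(puncta = puncta, mask = mask, params = params),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %d puncta\n", nrow(x$puncta)))
  invisible(x)
}

# Assign component pixels to their nearest local-maximum seed; used to split
# merged components that exceed max_area (a light-weight watershed stand-in
# on the LoG response).
.split_component <- function(idx_rc, resp) {
  vals <- resp[idx_rc]
  is_seed <- vapply(seq_len(nrow(idx_rc)), function(i) {
    r <- idx_rc[i, 1]; c <- idx_rc[i, 2]
    nb <- resp[pmax(1, r - 1):pmin(nrow(resp), r + 1),
               pmax(1, c - 1):pmin(ncol(resp), c + 1)]
    vals[i] >= max(nb)
  }, logical(1))
  seeds <- which(is_seed)
  if (length(seeds) < 2L) return(rep(1L, nrow(idx_rc)))
  d2 <- outer(idx_rc[, 1], idx_rc[seeds, 1], "-")^2 +
    outer(idx_rc[, 2], idx_rc[seeds, 2], "-")^2
  max.col(-d2, ties.method = "first")
}

#' Detect puncta by LoG filtering (optionally CLAHE-enhanced)
#'
#' The image is filtered with a scale-normalized LoG at each requested
#' scale, taking the per-pixel maximum response. Pixels whose response
#' exceeds `median + k_mad * MAD` (computed within the mask) form
#' 8-connected components; components larger than `max_area_px` are split by
#' nearest-local-maximum assignment, components within
#' `[min_area_px, max_area_px]` become puncta, and overlapping multi-scale
#' duplicates (blobs closer than the sum of their scale radii) are pruned,
#' keeping the stronger response.
#'
#' A punctum's reported `area_px` is measured on the intensity image, not
#' the response: the pixels connected to the punctum peak that lie above
#' half of its peak height over the local background (FWHM area). This is
#' independent of the filter scale, so relative size comparisons are
#' unbiased; `supra_px` keeps the raw supra-threshold response pixel count
#' (which the area filter applies to).
#'
#' The MAD threshold already makes detection invariant to global intensity
#' scaling; CLAHE (`enhance = TRUE`) additionally flattens uneven
#' illumination but amplifies background noise on already-flat scenes, so
#' it is off by default.
#'
#' @param raster a [raster_img()] or matrix.
#' @param mask optional parent-cell [cell_mask()].
#' @param sigma_px LoG scale(s) in px: one value for compact puncta
#'   (invadopodia, default 2), several (e.g. `c(2, 4, 8)`) for size-varying
#'   adhesions.
#' @param k_mad robust threshold multiplier.
#' @param min_area_px,max_area_px component-size filter, px.
#' @param enhance apply [clahe()] first (for uneven illumination).
#' @param tile_px,clip_limit CLAHE parameters when `enhance = TRUE`.
#' @return a [puncta_set()]; the `puncta` data.frame has columns `id`,
#'   `row`, `col` (response-weighted centroid), `area_px`, `area_um2`,
#'   `supra_px`, `mean_int`, `peak_response`, `scale_px`.
#' @export
detect_puncta <- function(raster, mask = NULL, sigma_px = 2, k_mad = 5,
                          min_area_px = 4L, max_area_px = Inf,
                          enhance = FALSE, tile_px = 64L, clip_limit = 0.01) {
  stopifnot(all(sigma_px >= 0.5), k_mad > 0, min_area_px >= 1)
  px <- .px(raster)
  img <- if (enhance) clahe(px, tile_px = tile_px, clip_limit = clip_limit)
         else px
  resps <- lapply(sigma_px, function(s) .log_filter(img, s))
  resp <- resps[[1L]]
  scale_of <- matrix(1L, nrow(px), ncol(px))
  if (length(resps) > 1L) for (i in 2:length(resps)) {
    better <- resps[[i]] > resp
    resp[better] <- resps[[i]][better]
    scale_of[better] <- i
  }
  m <- if (is.null(mask)) matrix(TRUE, nrow(px), ncol(px))
       else .mask_logical(mask, dim(px))
  med <- stats::median(resp[m]); madv <- stats::mad(resp[m])
  thr <- med + k_mad * madv
  bin <- resp > thr & m
  lab <- .label_components(bin)
  res <- list()
  psz <- .pixel_size(raster)
  # FWHM area on a lightly smoothed local window. Gaussian smoothing
  # (sigma 0.8 px) damps the upward bias of the noisy peak estimate while
  # keeping a Gaussian blob exactly Gaussian: it widens the half-max area by
  # 2*pi*ln2*0.64 px, which is subtracted analytically.
  fwhm_area <- function(sub, sigma) {
    pad <- ceiling(3 * sigma) + 3L
    r0 <- max(1L, min(sub[, 1]) - pad); r1 <- min(nrow(px), max(sub[, 1]) + pad)
    c0 <- max(1L, min(sub[, 2]) - pad); c1 <- min(ncol(px), max(sub[, 2]) + pad)
    k3 <- .gauss_kernel(0.8)
    win <- .conv1d(.conv1d(px[r0:r1, c0:c1, drop = FALSE], k3, 1L), k3, 2L)
    border <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
    bg <- stats::median(border)
    srows <- sub[, 1] - r0 + 1L; scols <- sub[, 2] - c0 + 1L
    peak <- max(win[cbind(srows, scols)])
    if (peak <= bg) return(nrow(sub))
    level <- bg + 0.5 * (peak - bg)
    wl <- .label_components(win >= level)
    pk <- which.max(win[cbind(srows, scols)])
    id <- wl[srows[pk], scols[pk]]
    if (id == 0L) return(nrow(sub))
    max(sum(wl == id) - 2 * pi * log(2) * 0.64, 1)
  }
  for (comp in seq_len(max(0, max(lab)))) {
    idx <- which(lab == comp, arr.ind = TRUE)
    pieces <- if (nrow(idx) > max_area_px)
      split(seq_len(nrow(idx)), .split_component(idx, resp))
    else list(seq_len(nrow(idx)))
    for (pc in pieces) {
      sub <- idx[pc, , drop = FALSE]
      n <- nrow(sub)
      if (n < min_area_px || n > max_area_px) next
      w <- resp[sub] - thr
      if (sum(w) <= 0) w <- rep(1, n)
      ctr_r <- sum(sub[, 1] * w) / sum(w)
      ctr_c <- sum(sub[, 2] * w) / sum(w)
      peak_i <- which.max(resp[sub])
      sc <- scale_of[sub[peak_i, , drop = FALSE]]
      area <- fwhm_area(sub, sigma_px[sc])
      res[[length(res) + 1L]] <- data.frame(
        row = ctr_r, col = ctr_c, area_px = area,
        area_um2 = area * psz^2, supra_px = n,
        mean_int = mean(px[sub]), peak_response = max(resp[sub]),
        scale_px = sigma_px[sc])
    }
  }
  if (length(res) > 1L && length(sigma_px) > 1L) {
    # prune overlapping multi-scale duplicates, strongest response first
    df0 <- do.call(rbind, res)
    ord <- order(df0$peak_response, decreasing = TRUE)
    keep <- logical(nrow(df0))
    for (i in ord) {
      ki <- which(keep)
      di <- sqrt((df0$row[ki] - df0$row[i])^2 + (df0$col[ki] - df0$col[i])^2)
      lim <- sqrt(2) * (df0$scale_px[ki] + df0$scale_px[i])
      if (!any(di < lim)) keep[i] <- TRUE
    }
    res <- res[sort(which(keep))]
  }
  df <- if (length(res)) cbind(id = seq_along(res), do.call(rbind, res))
        else data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                        area_px = numeric(0), area_um2 = numeric(0),
                        supra_px = integer(0), mean_int = numeric(0),
                        peak_response = numeric(0), scale_px = numeric(0))
  puncta_set(df, mask = mask,
             params = list(sigma_px = sigma_px, k_mad = k_mad,
                           min_area_px = min_area_px,
                           max_area_px = max_area_px, enhance = enhance,
                           threshold = thr))
}

#' Focal-adhesion size as fold difference to control
#'
#' Mean punctum area pooled over all sample cells divided by the pooled mean
#' over control cells (per-punctum mean, the default), or per-cell total
#' adhesion area averaged across cells (`mode = "per_cell_total"`).
#'
#' @param sample_sets,control_sets lists of [puncta_set()] (one per cell).
#' @param mode `"per_punctum"` or `"per_cell_total"`.
#' @return fold difference (scalar).
#' @export
adhesion_area_fold <- function(sample_sets, control_sets,
                               mode = c("per_punctum", "per_cell_total")) {
  mode <- match.arg(mode)
  pool <- function(sets) {
    if (inherits(sets, "puncta_set")) sets <- list(sets)
    if (mode == "per_punctum") {
      unlist(lapply(sets, function(s) s$puncta$area_px))
    } else {
      vapply(sets, function(s) sum(s$puncta$area_px), numeric(1))
    }
  }
  ctrl <- pool(control_sets)
  if (!length(ctrl) || sum(ctrl) == 0) stop("control has no puncta")
  mean(pool(sample_sets)) / mean(ctrl)
}

#' Invadopodia counts per cell
#'
#' Absolute number of detected puncta per cell and the across-cell mean (the
#' convention for invadopodia scoring: counts, not fold change).
#'
#' @param puncta_sets list of [puncta_set()] (one per cell).
#' @return `list(per_cell = integer vector, mean = scalar)`.
#' @export
invadopodia_count <- function(puncta_sets) {
  if (inherits(puncta_sets, "puncta_set")) puncta_sets <- list(puncta_sets)
  per_cell <- vapply(puncta_sets, function(s) nrow(s$puncta), integer(1))
  list(per_cell = per_cell,
       mean = if (length(per_cell)) mean(per_cell) else 0)
}

#' Intensity profile along a line segment
#'
#' Samples each channel by bilinear interpolation at evenly spaced points
#' along the segment from `p0` to `p1` (both included), at approximately the
#' requested step, producing the distance-vs-intensity table used for
#' colocalization line histograms.
#'
#' @param rasters a [raster_img()]/matrix or a (optionally named) list of them.
#' @param p0,p1 segment endpoints as `c(row, col)`, inside the image.
#' @param sampling_px target sampling step, px.
#' @return data.frame with `distance_px` and one intensity column per channel.
#' @export
line_profile <- function(rasters, p0, p1, sampling_px = 1) {
  if (!is.list(rasters) || inherits(rasters, "raster_img"))
    rasters <- list(intensity = rasters)
  mats <- lapply(rasters, .px)
  d <- dim(mats[[1L]])
  for (p in list(p0, p1))
    if (p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2])
      stop("profile endpoints must lie inside the image")
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(1L, round(len / sampling_px))
  tt <- seq(0, 1, length.out = n + 1L)
  rr <- p0[1] + tt * (p1[1] - p0[1])
  cc <- p0[2] + tt * (p1[2] - p0[2])
  out <- data.frame(distance_px = tt * len)
  nms <- names(rasters)
  if (is.null(nms) || any(nms == ""))
    nms <- paste0("channel_", seq_along(rasters))
  for (i in seq_along(mats)) out[[nms[i]]] <- .bilinear(mats[[i]], rr, cc)
  out
}
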