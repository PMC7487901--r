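# Cytometry, densitometry and morphometry quantifications.

# Locate the 2n (G0/G1) peak of a DNA-content histogram: take the strongest
# density mode, but if a comparable mode sits at half its position the
# strongest mode is the 4n peak of a G2/M-dominated sample and the half-
# position mode is the true 2n peak.
.find_2n_peak <- function(v) {
  if (diff(range(v)) < .Machine$double.eps * max(v)) return(v[1])
  d <- stats::density(v, n = 1024)
  ispk <- which(diff(sign(diff(d$y))) == -2) + 1L
  if (!length(ispk)) stop("no detectable 2n mode in the PI histogram")
  peaks <- data.frame(x = d$x[ispk], y = d$y[ispk])
  main <- peaks[which.max(peaks$y), ]
  half <- peaks[abs(peaks$x - main$x / 2) < 0.1 * main$x & peaks$y >
                  0.25 * main$y, , drop = FALSE]
  if (nrow(half)) half$x[which.max(half$y)] else main$x
}

#' Gate DNA-content events into cell-cycle phases
#'
#' Phases are defined by ploidy: G0/G1 at 2n, G2/M at 4n (= 2 x the detected
#' 2n mode), S strictly in between. Gates are `2n * (1 +/- k * CV)` and
#' `4n * (1 +/- k * CV)` (half-open `[low, high)`), with the peak CV
#' estimated robustly around the 2n mode; events below the G0/G1 gate
#' (sub-G1) or above the G2/M gate (> 4n) are excluded from the denominator.
#'
#' Raw gate counts systematically misassign the S-phase bridge that runs
#' into the (wide) 4n gate, so the reported `fractions` are by default
#' corrected for the expected gate spillover by solving the 3 x 3 linear
#' system that maps true class counts to expected gate counts (no curve
#' fitting involved); `fractions_raw` keeps the uncorrected gate counts.
#'
#' @param pi_values PI fluorescence per event (>= 100 events).
#' @param cv_window_k gate half-width in units of peak CV.
#' @param correct_spillover apply the linear spillover correction.
#' @return `list(fractions, fractions_raw, labels, n_events, n_gated,
#'   peak_2n, peak_4n, cv)`; both fraction vectors are named
#'   `(g0g1, s, g2m)` and sum to 1.
#' @export
gate_cell_cycle <- function(pi_values, cv_window_k = 2,
                            correct_spillover = TRUE) {
  v <- pi_values[is.finite(pi_values) & pi_values > 0]
  if (length(v) < 100L) stop("need at least 100 events")
  p2 <- .find_2n_peak(v)
  p4 <- 2 * p2
  near <- v[v > 0.85 * p2 & v < 1.15 * p2]
  cv <- max(stats::mad(near, center = p2) / p2, 0.005)
  k <- cv_window_k
  g1_lo <- p2 * (1 - k * cv); g1_hi <- p2 * (1 + k * cv)
  g2_lo <- p4 * (1 - k * cv); g2_hi <- p4 * (1 + k * cv)
  lab <- rep(NA_character_, length(v))
  lab[v >= g1_lo & v < g1_hi] <- "g0g1"
  lab[v >= g1_hi & v < g2_lo] <- "s"
  lab[v >= g2_lo & v < g2_hi] <- "g2m"
  gated <- !is.na(lab)
  if (!any(gated)) stop("no events fall inside the cell-cycle gates")
  counts <- c(g0g1 = sum(lab == "g0g1", na.rm = TRUE),
              s = sum(lab == "s", na.rm = TRUE),
              g2m = sum(lab == "g2m", na.rm = TRUE))
  raw <- counts / sum(counts)
  fractions <- raw
  if (correct_spillover) {
    q <- 2 * stats::pnorm(k) - 1          # peak mass inside its own gate
    tl <- 1 - stats::pnorm(k)             # one-sided peak tail into S
    # uniform S bridge on (2n, 4n): overlap with each gate, relative widths
    sA <- min(k * cv, 1); sC <- min(2 * k * cv, 1)
    sB <- max(1 - sA - sC, 0)
    M <- rbind(c(q, sA, 0),
               c(tl, sB, tl),
               c(0, sC, q))
    est <- tryCatch(solve(M, as.numeric(counts)), error = function(e) NULL)
    if (!is.null(est)) {
      est <- pmax(est, 0)
      est[counts == 0] <- 0   # never invent a class with an empty gate
      if (sum(est) > 0) fractions <- stats::setNames(est / sum(est), names(counts))
    }
  }
  list(fractions = fractions, fractions_raw = raw,
       labels = lab, n_events = length(v), n_gated = sum(gated),
       peak_2n = p2, peak_4n = p4, cv = cv)
}

#' Quadrant classification of Annexin V / PI events
#'
#' Live cells stain with neither dye; early apoptotic cells are Annexin-
#' positive only; necrotic cells stain with both; PI-only events are
#' reported as "other". Thresholds default to per-channel Otsu cuts on
#' log10-transformed values.
#'
#' @param events data.frame with columns `annexin` and `pi`.
#' @param thresholds optional `c(annexin =, pi =)` on the linear scale.
#' @return `list(fractions, labels, thresholds)`; fractions are named
#'   `(live, early_apoptotic, necrotic, other)` and sum to 1.
#' @export
classify_annexin_pi <- function(events, thresholds = NULL) {
  stopifnot(all(c("annexin", "pi") %in% names(events)))
  a <- events$annexin; p <- events$pi
  if (is.null(thresholds)) {
    # Per-channel cut at the density valley between the negative and
    # positive populations; a unimodal channel is treated as all-negative
    # with the cut placed well above its single mode.
    cut1 <- function(x) {
      lx <- log10(pmax(x, .Machine$double.xmin))
      if (diff(range(lx)) < 1e-9) return(10^(max(lx) + 1))
      d <- stats::density(lx, n = 512)
      ipk <- which(diff(sign(diff(d$y))) == -2) + 1L
      ipk <- ipk[d$y[ipk] >= 0.05 * max(d$y)]
      if (length(ipk) < 2L)
        return(10^(d$x[which.max(d$y)] + 5 * stats::mad(lx)))
      top2 <- sort(ipk[order(d$y[ipk], decreasing = TRUE)][1:2])
      valley <- top2[1] + which.min(d$y[top2[1]:top2[2]]) - 1L
      10^d$x[valley]
    }
    thresholds <- c(annexin = cut1(a), pi = cut1(p))
  }
  ap <- a >= thresholds[["annexin"]]; pp <- p >= thresholds[["pi"]]
  lab <- ifelse(!ap & !pp, "live",
                ifelse(ap & !pp, "early_apoptotic",
                       ifelse(ap & pp, "necrotic", "other")))
  lv <- c("live", "early_apoptotic", "necrotic", "other")
  fr <- vapply(lv, function(k) mean(lab == k), numeric(1))
  list(fractions = fr, labels = lab, thresholds = thresholds)
}

#' Densitometry fold change versus a control lane
#'
#' Each lane's band intensity is normalized to its loading control; folds
#' are the normalized values relative to the control lane, making the
#' result exactly invariant to per-replicate exposure changes.
#'
#' @param bands data.frame with columns `lane`, `band`, `loading`.
#' @param control_lane label of the control lane (e.g. the luciferase lane).
#' @return `bands` with added columns `normalized` and `fold`.
#' @export
densitometry_fold <- function(bands, control_lane) {
  stopifnot(all(c("lane", "band", "loading") %in% names(bands)))
  if (!control_lane %in% bands$lane)
    stop("control lane not present: ", control_lane)
  if (any(bands$loading <= 0)) stop("loading intensities must be > 0")
  bands$normalized <- bands$band / bands$loading
  ctrl <- bands$normalized[match(control_lane, bands$lane)]
  if (ctrl <= 0) stop("control normalized intensity must be > 0")
  bands$fold <- bands$normalized / ctrl
  bands
}

#' Sphere morphometry from diameter or mask
#'
#' Projected area `pi d^2 / 4` and (assuming sphericity) volume
#' `pi d^3 / 6`. When a mask is given, d is the equivalent-circle diameter
#' of the projected area.
#'
#' @param diameter_um sphere diameter(s), um; or
#' @param mask a [cell_mask()] of the projected sphere.
#' @param pixel_size_um um per pixel when a mask is used.
#' @return data.frame: `diameter_um`, `area_um2`, `volume_um3`.
#' @export
sphere_metrics <- function(diameter_um = NULL, mask = NULL,
                           pixel_size_um = 1) {
  if (is.null(diameter_um)) {
    if (is.null(mask)) stop("give a diameter or a mask")
    area_px <- sum(.mask_logical(mask))
    if (area_px == 0) stop("sphere mask is empty")
    diameter_um <- 2 * sqrt(area_px / pi) * pixel_size_um
  }
  if (any(diameter_um <= 0)) stop("diameters must be > 0")
  data.frame(diameter_um = diameter_um,
             area_um2 = pi * diameter_um^2 / 4,
             volume_um3 = pi * diameter_um^3 / 6)
}

#' Mean fluorescence intensity per pixel over fixed-area frames
#'
#' Per-frame mean intensity for tissue frames of identical shape, optionally
#' compared between two groups as `mean(group A) / mean(group B)`.
#'
#' @param rasters list of [raster_img()]/matrices, all the same shape.
#' @param groups optional factor/character vector (two levels) assigning
#'   frames to groups; the fold is first level over second.
#' @return data.frame `(frame, group, mean_intensity)`, with attribute
#'   `group_fold` when `groups` is given.
#' @export
tissue_mean_intensity <- function(rasters, groups = NULL) {
  mats <- lapply(rasters, .px)
  d <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("all frames must share one shape (fixed-area convention)")
  means <- vapply(mats, mean, numeric(1))
  out <- data.frame(frame = seq_along(mats),
                    group = if (is.null(groups)) NA_character_
                            else as.character(groups),
                    mean_intensity = means)
  if (!is.null(groups)) {
    gl <- unique(as.character(groups))
    if (length(gl) != 2L) stop("groups must have exactly two levels")
    attr(out, "group_fold") <- mean(means[groups == gl[1]]) /
      mean(means[groups == gl[2]])
  }
  out
}
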