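# Synthetic-scene generators.
#
# Each generator stands in for one class of raw data the supported assays
# consume (FRET channel triplets, fluorescent-gelatin fields, punctate
# immunostains, wound-healing mask series, random-motility tracks, flow
# cytometry events, gel densitometry tables) and returns the generated data
# together with a ground-truth record, so every analysis stage can be
# validated against a known answer. Identical seeds give bit-identical
# scenes; noise, placement and sampling use separate named RNG streams.

.noise_channel <- function(expected, poisson, read_sd) {
  out <- expected
  if (poisson) out <- matrix(stats::rpois(length(out), out), nrow(out), ncol(out))
  if (read_sd > 0) out <- out + stats::rnorm(length(out), 0, read_sd)
  pmax(out, 0)
}

#' Simulate a FRET biosensor scene (donor / FRET / acceptor triplet)
#'
#' An elliptical cell of uniform donor brightness sits on a noisy background.
#' The per-pixel true activation ratio is a baseline, optionally multiplied
#' by a factor over a "tail hotspot": the fraction of cell pixels furthest
#' along the major axis, emulating persistent GTPase activation at the tail
#' of a cell that cannot detach.
#'
#' @param shape image size `c(rows, cols)` in px.
#' @param center,axes,theta cell ellipse: centre (row, col), semi-axes
#'   `c(along rows, along cols)` in px, rotation in radians.
#' @param donor_level mean donor intensity inside the cell (photon counts).
#' @param background_level camera background added to every channel.
#' @param ratio_baseline true FRET/donor ratio inside the cell.
#' @param hotspot optional `list(factor =, fraction =)`: multiply the ratio by
#'   `factor` over the tail `fraction` of cell pixels.
#' @param noise `list(poisson =, read_sd =)`; Poisson shot noise on expected
#'   counts plus Gaussian read noise. Set both off for analytic tests.
#' @param acceptor_level mean acceptor (YFP) intensity inside the cell,
#'   used only for masking.
#' @param pixel_size_um physical pixel size recorded on the rasters.
#' @param seed scene seed.
#' @return `list(images, mask, truth)`: a [fret_image_set()], the true cell
#'   [cell_mask()], and the ground truth (`mean_ratio` is the area-weighted
#'   mean of the true ratio map over the cell).
#' @export
make_fret_scene <- function(shape = c(160L, 160L),
                            center = shape / 2, axes = c(35, 52), theta = 0,
                            donor_level = 1000, background_level = 100,
                            ratio_baseline = 1.0, hotspot = NULL,
                            noise = list(poisson = TRUE, read_sd = 20),
                            acceptor_level = donor_level,
                            pixel_size_um = 1, seed = 1L) {
  stopifnot(donor_level > background_level, background_level >= 0,
            ratio_baseline > 0)
  brad <- max(axes)
  if (center[1] - brad < 1 || center[1] + brad > shape[1] ||
      center[2] - brad < 1 || center[2] + brad > shape[2])
    stop("cell ellipse exceeds the image")
  inside <- .ellipse_mask(shape, center, axes, theta)
  ratio_map <- matrix(1, shape[1], shape[2])
  ratio_map[inside] <- ratio_baseline
  if (!is.null(hotspot)) {
    stopifnot(hotspot$factor > 0, hotspot$fraction >= 0, hotspot$fraction <= 1)
    idx <- which(inside, arr.ind = TRUE)
    u <- (idx[, 2] - center[2]) * cos(theta) + (idx[, 1] - center[1]) * sin(theta)
    n_hot <- round(hotspot$fraction * nrow(idx))
    if (n_hot > 0) {
      hot <- idx[order(u, decreasing = TRUE)[seq_len(n_hot)], , drop = FALSE]
      ratio_map[hot] <- ratio_map[hot] * hotspot$factor
    }
  }
  donor_sig <- background_level + donor_level * inside
  fret_sig  <- background_level + donor_level * inside * ratio_map
  acc_sig   <- background_level + acceptor_level * inside
  poisson <- isTRUE(noise$poisson)
  read_sd <- if (is.null(noise$read_sd)) 0 else noise$read_sd
  ch <- .with_stream(seed, "fret-noise", list(
    donor = .noise_channel(donor_sig, poisson, read_sd),
    fret = .noise_channel(fret_sig, poisson, read_sd),
    acceptor = .noise_channel(acc_sig, poisson, read_sd)))
  images <- fret_image_set(
    raster_img(ch$donor, pixel_size_um), raster_img(ch$fret, pixel_size_um),
    raster_img(ch$acceptor, pixel_size_um))
  truth <- list(mean_ratio = mean(ratio_map[inside]), ratio_map = ratio_map,
                cell_area_px = sum(inside), donor_level = donor_level,
                background_level = background_level, seed = seed)
  list(images = images, mask = cell_mask(inside), truth = truth)
}

# Depth map for a set of circular degradation spots; overlaps combine by
# per-pixel maximum depth (re-degradation cannot un-degrade).
.spot_depth_map <- function(shape, spots) {
  depth <- matrix(0, shape[1], shape[2])
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (s in spots) {
    d2 <- (rr - s$center[1])^2 + (cc - s$center[2])^2
    hit <- d2 <= s$radius^2
    depth[hit] <- pmax(depth[hit], s$depth)
  }
  depth
}

#' Simulate a fluorescent-gelatin matrix degradation scene
#'
#' Uniform labelled gelatin with dark circular degradation spots under an
#' elliptical cell footprint. Spots may be given explicitly or placed at
#' random until a requested fraction of the footprint is degraded (the last
#' spot is trimmed so the realized fraction matches to one pixel).
#'
#' @param shape image size `c(rows, cols)` px.
#' @param matrix_level intact gelatin fluorescence.
#' @param center,axes,theta cell footprint ellipse (px).
#' @param spots explicit list of `list(center = c(r, c), radius =, depth =)`
#'   with depth in `[0, 1]` (1 = fully degraded).
#' @param degraded_fraction target fraction of footprint pixels degraded;
#'   ignored when `spots` is given.
#' @param depth,radius_range depth and radius range (px) for random spots.
#' @param noise_sd Gaussian noise sd.
#' @param clip_to_footprint confine degradation to the footprint. The default
#'   (`FALSE`) lets spots spill slightly past the cell edge, as under a
#'   motile cell; `TRUE` gives the analytic construction in which the
#'   surrounding matrix stays exactly pristine.
#' @param pixel_size_um physical pixel size.
#' @param seed scene seed.
#' @return `list(matrix, mask, truth)`: the matrix [raster_img()], footprint
#'   [cell_mask()], and truth (per-pixel `depth_map`, realized
#'   `degraded_fraction` within the footprint, spot list, expected cell and
#'   background means).
#' @export
make_matrix_scene <- function(shape = c(192L, 192L), matrix_level = 1000,
                              center = shape / 2, axes = c(45, 60), theta = 0,
                              spots = NULL, degraded_fraction = NULL,
                              depth = 1, radius_range = c(3, 6),
                              noise_sd = 0, clip_to_footprint = FALSE,
                              pixel_size_um = 1, seed = 1L) {
  stopifnot(matrix_level > 0, noise_sd >= 0)
  footprint <- .ellipse_mask(shape, center, axes, theta)
  fp_idx <- which(footprint)
  if (is.null(spots)) spots <- list()
  stopifnot(all(vapply(spots, function(s) s$depth >= 0 && s$depth <= 1 &&
                         s$center[1] >= 1 && s$center[1] <= shape[1] &&
                         s$center[2] >= 1 && s$center[2] <= shape[2],
                       logical(1))))
  depth_map <- .spot_depth_map(shape, spots)
  if (!is.null(degraded_fraction) && length(spots) == 0L) {
    stopifnot(degraded_fraction >= 0, degraded_fraction <= 1, depth >= 0,
              depth <= 1)
    target <- round(degraded_fraction * length(fp_idx))
    spots <- .with_stream(seed, "matrix-placement", {
      acc <- list()
      while (sum(depth_map[fp_idx] > 0) < target) {
        i <- fp_idx[sample.int(length(fp_idx), 1L)]
        ctr <- c((i - 1L) %% shape[1] + 1L, (i - 1L) %/% shape[1] + 1L)
        s <- list(center = ctr,
                  radius = stats::runif(1, radius_range[1], radius_range[2]),
                  depth = depth)
        new_map <- .spot_depth_map(shape, list(s))
        excess <- sum((depth_map[fp_idx] > 0 | new_map[fp_idx] > 0)) - target
        if (excess > 0) {  # trim the final spot, farthest pixels first
          cand <- which(new_map > 0 & depth_map == 0 & footprint)
          rr <- (cand - 1L) %% shape[1] + 1L; cc <- (cand - 1L) %/% shape[1] + 1L
          d2 <- (rr - ctr[1])^2 + (cc - ctr[2])^2
          drop <- cand[order(d2, decreasing = TRUE)[seq_len(min(excess, length(cand)))]]
          new_map[drop] <- 0
        }
        depth_map <- pmax(depth_map, new_map)
        acc[[length(acc) + 1L]] <- s
      }
      acc
    })
  }
  if (clip_to_footprint) depth_map[!footprint] <- 0
  expected <- matrix_level * (1 - depth_map)
  pixels <- if (noise_sd > 0)
    .with_stream(seed, "matrix-noise",
                 pmax(expected + stats::rnorm(length(expected), 0, noise_sd), 0))
  else expected
  realized <- mean(depth_map[fp_idx] > 0)
  truth <- list(depth_map = depth_map, degraded_fraction = realized,
                spots = spots, matrix_level = matrix_level,
                cell_mean_expected = matrix_level * mean(1 - depth_map[fp_idx]),
                background_mean_expected =
                  matrix_level * mean(1 - depth_map[-fp_idx]),
                seed = seed)
  list(matrix = raster_img(matrix(pixels, shape[1], shape[2]), pixel_size_um),
       mask = cell_mask(footprint), truth = truth)
}

#' Simulate a punctate immunostain field (vinculin / TKS4 style)
#'
#' Gaussian-profile spots on a flat or linearly graded background. A spot of
#' nominal radius r has intensity profile `peak * exp(-d^2 / (2 s^2))` with
#' `s = r / sqrt(2)`, so the best-matching Laplacian-of-Gaussian scale is
#' `sigma = r / sqrt(2)`. Placement enforces a minimum separation unless
#' overlap is explicitly allowed.
#'
#' @param shape image size `c(rows, cols)` px.
#' @param n_puncta number of spots.
#' @param radius_range nominal spot radius range, px (>= 1).
#' @param peak peak spot intensity above background.
#' @param background background level.
#' @param gradient_amp amplitude of a left-to-right linear background ramp.
#' @param noise_sd Gaussian noise sd.
#' @param mask optional parent-cell [cell_mask()]; spots are placed inside it.
#' @param min_sep minimum centre separation, px; default `6 * max(radius)`.
#' @param centers,radii explicit spot placement (n x 2 matrix of (row, col)
#'   and a radius vector), bypassing random placement — e.g. to build paired
#'   conditions that differ only in spot size.
#' @param allow_overlap skip the separation constraint.
#' @param max_tries placement retries per spot before a placement error.
#' @param pixel_size_um physical pixel size.
#' @param seed scene seed.
#' @return `list(image, mask, truth)`; truth stores continuous spot centres,
#'   radii and nominal areas (`pi * r^2` px).
#' @export
make_puncta_scene <- function(shape = c(192L, 192L), n_puncta = 12L,
                              radius_range = c(2, 4), peak = 500,
                              background = 100, gradient_amp = 0,
                              noise_sd = 20, mask = NULL, min_sep = NULL,
                              centers = NULL, radii = NULL,
                              allow_overlap = FALSE, max_tries = 2000L,
                              pixel_size_um = 1, seed = 1L) {
  stopifnot(n_puncta >= 0, radius_range[1] >= 1, peak > 0, noise_sd >= 0)
  if (is.null(min_sep)) min_sep <- 6 * radius_range[2]
  inside <- if (is.null(mask)) matrix(TRUE, shape[1], shape[2])
            else .mask_logical(mask, shape)
  margin <- ceiling(3 * radius_range[2])
  placement <- if (!is.null(centers)) {
    stopifnot(!is.null(radii), nrow(centers) == length(radii),
              all(radii >= 1))
    n_puncta <- length(radii)
    list(centers = centers, radii = radii)
  } else .with_stream(seed, "puncta-placement", {
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    for (i in seq_len(n_puncta)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        r <- stats::runif(1, 1 + margin, shape[1] - margin)
        c <- stats::runif(1, 1 + margin, shape[2] - margin)
        if (!inside[round(r), round(c)]) next
        if (!allow_overlap && nrow(centers) > 0 &&
            min((centers[, 1] - r)^2 + (centers[, 2] - c)^2) < min_sep^2) next
        centers <- rbind(centers, c(r, c)); ok <- TRUE; break
      }
      if (!ok) stop("could not place ", n_puncta,
                    " puncta without overlap (placement error)")
      radii <- c(radii, stats::runif(1, radius_range[1], radius_range[2]))
    }
    list(centers = centers, radii = radii)
  })
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  img <- background + gradient_amp * (cc - 1) / max(1, shape[2] - 1)
  for (i in seq_len(n_puncta)) {
    s <- placement$radii[i] / sqrt(2)
    d2 <- (rr - placement$centers[i, 1])^2 + (cc - placement$centers[i, 2])^2
    img <- img + peak * exp(-d2 / (2 * s^2))
  }
  if (noise_sd > 0)
    img <- .with_stream(seed, "puncta-noise",
                        pmax(img + stats::rnorm(length(img), 0, noise_sd), 0))
  truth <- list(centers = placement$centers, radii = placement$radii,
                areas_px = pi * placement$radii^2, peak = peak,
                background = background, seed = seed)
  list(image = raster_img(matrix(img, shape[1], shape[2]), pixel_size_um),
       mask = cell_mask(inside), truth = truth)
}

#' Simulate persistent-random-walk cell tracks
#'
#' Each cell takes steps of fixed length with a heading that evolves by a
#' wrapped-Gaussian turn; the turn spread maps from the persistence p via
#' `sd = sqrt(-2 log p)` so that the expected cosine of the turn equals p.
#' Emulates random-motility time lapse (default: a frame every minute for
#' 2 h, control-like speed 0.3 um/min).
#'
#' @param n_cells number of tracks.
#' @param n_frames frames per track.
#' @param frame_interval_min minutes between frames.
#' @param step_um fixed step length per frame, um.
#' @param persistence directional persistence in `[0, 1]` (1 = straight line).
#' @param loc_noise_sd_um localization noise added to reported positions, um.
#' @param field_um cells start uniformly in this `c(width, height)` um field.
#' @param seed scene seed.
#' @return `list(tracks, truth)`: a [track_table()] and per-track truth
#'   (exact total path length, net displacement, speed) computed from the
#'   noiseless paths.
#' @export
make_track_set <- function(n_cells = 15L, n_frames = 120L,
                           frame_interval_min = 1, step_um = 0.3,
                           persistence = 0.6, loc_noise_sd_um = 0,
                           field_um = c(400, 400), seed = 1L) {
  stopifnot(n_cells >= 1, n_frames >= 2, persistence >= 0, persistence <= 1,
            step_um >= 0, loc_noise_sd_um >= 0)
  sd_turn <- if (persistence == 0) Inf else sqrt(-2 * log(max(persistence, 1e-12)))
  sim <- .with_stream(seed, "tracks-sampling", {
    rows <- vector("list", n_cells)
    truth <- vector("list", n_cells)
    for (id in seq_len(n_cells)) {
      x <- stats::runif(1, 0, field_um[1]); y <- stats::runif(1, 0, field_um[2])
      th <- stats::runif(1, 0, 2 * pi)
      xs <- numeric(n_frames); ys <- numeric(n_frames)
      xs[1] <- x; ys[1] <- y
      for (f in 2:n_frames) {
        if (is.infinite(sd_turn)) th <- stats::runif(1, 0, 2 * pi)
        else th <- th + stats::rnorm(1, 0, sd_turn)
        x <- x + step_um * cos(th); y <- y + step_um * sin(th)
        xs[f] <- x; ys[f] <- y
      }
      ox <- xs; oy <- ys
      if (loc_noise_sd_um > 0) {
        ox <- xs + stats::rnorm(n_frames, 0, loc_noise_sd_um)
        oy <- ys + stats::rnorm(n_frames, 0, loc_noise_sd_um)
      }
      total <- step_um * (n_frames - 1)
      net <- sqrt((xs[n_frames] - xs[1])^2 + (ys[n_frames] - ys[1])^2)
      rows[[id]] <- data.frame(track_id = id, frame = seq_len(n_frames),
                               x = ox, y = oy)
      truth[[id]] <- data.frame(track_id = id, total_path_um = total,
                                net_um = net,
                                speed_um_min = total /
                                  ((n_frames - 1) * frame_interval_min))
    }
    list(rows = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
  list(tracks = track_table(sim$rows, frame_interval_min),
       truth = list(per_track = sim$truth, step_um = step_um,
                    persistence = persistence, seed = seed,
                    mean_speed_um_min = mean(sim$truth$speed_um_min)))
}

#' Simulate a wound-healing mask series
#'
#' A vertical cell-free band of width `w(t) = max(0, w0 - rate * t)` in a
#' confluent monolayer. Edge roughness is a fixed, zero-mean smooth profile
#' per edge (drawn once per scene), so a zero closure rate reproduces
#' identical frames.
#'
#' @param shape_px mask size `c(rows, cols)`.
#' @param pixel_size_um um per pixel.
#' @param width0_um initial wound width, um.
#' @param rate_um_hr true closure rate, um per hour.
#' @param times_hr acquisition times in hours.
#' @param roughness_um edge roughness amplitude, um (0 = straight edges).
#' @param seed scene seed.
#' @return `list(masks, truth)`: one [cell_mask()] per time point (1 = cells,
#'   0 = wound) and truth widths `w(t)`.
#' @export
make_wound_series <- function(shape_px = c(300L, 400L), pixel_size_um = 2,
                              width0_um = 500, rate_um_hr = 5,
                              times_hr = c(0, 48), roughness_um = 8,
                              seed = 1L) {
  stopifnot(width0_um >= 0, pixel_size_um > 0, roughness_um >= 0)
  nr <- shape_px[1]; nc <- shape_px[2]
  rough <- .with_stream(seed, "wound-roughness", {
    mk <- function() {
      if (roughness_um == 0) return(numeric(nr))
      t <- seq_len(nr)
      p <- roughness_um * (sin(2 * pi * (2.0 * t / nr + stats::runif(1))) +
                           0.6 * sin(2 * pi * (3.7 * t / nr + stats::runif(1))))
      p - mean(p)
    }
    list(left = mk(), right = mk())
  })
  center_x <- nc / 2 * pixel_size_um
  x <- (seq_len(nc) - 0.5) * pixel_size_um
  masks <- lapply(times_hr, function(t) {
    w <- max(0, width0_um - rate_um_hr * t)
    left <- center_x - w / 2 + rough$left
    right <- center_x + w / 2 + rough$right
    m <- matrix(1L, nr, nc)
    if (w > 0) {
      for (r in seq_len(nr)) m[r, x > left[r] & x < right[r]] <- 0L
    }
    cell_mask(m)
  })
  truth <- list(widths_um = pmax(0, width0_um - rate_um_hr * times_hr),
                times_hr = times_hr, rate_um_hr = rate_um_hr,
                width0_um = width0_um, pixel_size_um = pixel_size_um,
                seed = seed)
  list(masks = masks, truth = truth)
}

#' Simulate propidium-iodide DNA-content events
#'
#' G0/G1 events draw from a lognormal peak at the 2n position, G2/M from a
#' lognormal peak at 4n (= 2 x 2n), and S-phase events bridge the two peaks
#' uniformly, mirroring DNA content between 2n and 4n.
#'
#' @param n_events number of events (>= 1).
#' @param fractions `c(g0g1, s, g2m)`, non-negative, summing to 1.
#' @param cv coefficient of variation of the PI peaks (> 0).
#' @param peak_2n 2n peak position, arbitrary fluorescence units.
#' @param seed scene seed.
#' @return `list(events, truth)`: `events` is a data.frame with column `pi`;
#'   truth holds per-event phase labels and the realized class fractions.
#' @export
make_cytometry_events <- function(n_events = 10000L,
                                  fractions = c(0.6, 0.2, 0.2), cv = 0.05,
                                  peak_2n = 200, seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8, cv > 0, n_events >= 1)
  sim <- .with_stream(seed, "cytometry-sampling", {
    lab <- sample(c("g0g1", "s", "g2m"), n_events, replace = TRUE,
                  prob = fractions)
    sdlog <- sqrt(log(1 + cv^2))
    v <- numeric(n_events)
    v[lab == "g0g1"] <- stats::rlnorm(sum(lab == "g0g1"), log(peak_2n), sdlog)
    v[lab == "g2m"] <- stats::rlnorm(sum(lab == "g2m"), log(2 * peak_2n), sdlog)
    v[lab == "s"] <- stats::runif(sum(lab == "s"), peak_2n, 2 * peak_2n)
    list(pi = v, label = lab)
  })
  truth_frac <- c(g0g1 = mean(sim$label == "g0g1"), s = mean(sim$label == "s"),
                  g2m = mean(sim$label == "g2m"))
  list(events = data.frame(pi = sim$pi),
       truth = list(labels = sim$label, fractions = truth_frac,
                    requested_fractions = stats::setNames(
                      fractions, c("g0g1", "s", "g2m")),
                    peak_2n = peak_2n, cv = cv, seed = seed))
}

#' Simulate Annexin V / propidium-iodide bivariate events
#'
#' Three lognormal clusters: live (double negative), early apoptotic
#' (Annexin-positive only) and necrotic (double positive), separated by a
#' stated number of decades on each positive channel.
#'
#' @param n_events number of events.
#' @param fractions `c(live, early_apoptotic, necrotic)` summing to 1.
#' @param separation_dec decades between negative and positive cluster
#'   centres on a channel.
#' @param spread_dec within-cluster sd in decades.
#' @param seed scene seed.
#' @return `list(events, truth)`; events have columns `annexin`, `pi`.
#' @export
make_annexin_events <- function(n_events = 10000L,
                                fractions = c(0.7, 0.2, 0.1),
                                separation_dec = 1.2, spread_dec = 0.15,
                                seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8, separation_dec > 0, spread_dec > 0)
  base <- 2; hi <- base + separation_dec
  centers <- list(live = c(base, base), early_apoptotic = c(hi, base),
                  necrotic = c(hi, hi))
  sim <- .with_stream(seed, "annexin-sampling", {
    lab <- sample(names(centers), n_events, replace = TRUE, prob = fractions)
    ctr <- do.call(rbind, centers[lab])
    ann <- 10^(stats::rnorm(n_events, ctr[, 1], spread_dec))
    pi <- 10^(stats::rnorm(n_events, ctr[, 2], spread_dec))
    list(annexin = ann, pi = pi, label = lab)
  })
  truth_frac <- vapply(names(centers), function(k) mean(sim$label == k),
                       numeric(1))
  list(events = data.frame(annexin = sim$annexin, pi = sim$pi),
       truth = list(labels = sim$label, fractions = truth_frac,
                    requested_fractions = stats::setNames(
                      fractions, names(centers)), seed = seed))
}

#' Simulate gel densitometry lanes
#'
#' Band and loading-control intensities with multiplicative (lognormal)
#' measurement noise; the ground truth keeps the noiseless values.
#'
#' @param band_intensities true band intensities per lane (> 0).
#' @param loading_intensities true loading-control intensities per lane.
#' @param noise_cv multiplicative noise CV (0 = noiseless).
#' @param lanes optional lane labels.
#' @param seed scene seed.
#' @return `list(bands, truth)`: a data.frame `(lane, band, loading)` plus
#'   truth with noiseless values and true normalized ratios.
#' @export
make_gel_lanes <- function(band_intensities, loading_intensities,
                           noise_cv = 0, lanes = NULL, seed = 1L) {
  stopifnot(length(band_intensities) == length(loading_intensities),
            all(band_intensities > 0), all(loading_intensities > 0),
            noise_cv >= 0)
  n <- length(band_intensities)
  if (is.null(lanes)) lanes <- paste0("lane", seq_len(n))
  obs <- .with_stream(seed, "gel-noise", {
    f <- function(v) if (noise_cv > 0)
      v * stats::rlnorm(n, 0, sqrt(log(1 + noise_cv^2))) else v
    list(band = f(band_intensities), loading = f(loading_intensities))
  })
  list(bands = data.frame(lane = lanes, band = obs$band, loading = obs$loading,
                          stringsAsFactors = FALSE),
       truth = list(band = band_intensities, loading = loading_intensities,
                    normalized = band_intensities / loading_intensities,
                    seed = seed))
}
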