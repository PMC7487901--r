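# Wound-healing and random-motility statistics.

#' Wound widths at evenly spaced measurement lines
#'
#' The wound is the cell-free (0) band crossing the mask; at `n_lines`
#' evenly spaced rows, the width is the length of the longest 0-run in that
#' row times the pixel size. Rows with no wound pixels report width 0 (a
#' `closed` flag is attached).
#'
#' @param wound_mask a [cell_mask()] with 1 = cells, 0 = wound.
#' @param n_lines number of measurement lines (the assay convention is 11).
#' @param pixel_size_um um per pixel.
#' @param horizontal set `TRUE` for a wound band running horizontally
#'   (the mask is transposed first).
#' @return numeric vector of `n_lines` widths (um), with attribute `closed`
#'   flagging lines with no wound.
#' @export
wound_widths <- function(wound_mask, n_lines = 11L, pixel_size_um = 1,
                         horizontal = FALSE) {
  stopifnot(n_lines >= 1, pixel_size_um > 0)
  m <- .px(wound_mask)
  if (horizontal) m <- t(m)
  rows <- unique(round(seq(1, nrow(m), length.out = n_lines)))
  if (length(rows) < n_lines)  # tiny masks: reuse rows rather than drop lines
    rows <- round(seq(1, nrow(m), length.out = n_lines))
  widths <- vapply(rows, function(r) {
    v <- m[r, ] == 0
    if (!any(v)) return(0)
    runs <- rle(v)
    max(runs$lengths[runs$values]) * pixel_size_um
  }, numeric(1))
  attr(widths, "closed") <- widths == 0
  widths
}

#' Average wound closure rate in um/hr
#'
#' `(mean(widths at t0) - mean(widths at t1)) / elapsed_hr`; negative if the
#' gap widened. Uses first/last frames only, matching how the assay is read
#' out from two time points.
#'
#' @param widths_t0,widths_t1 width vectors from [wound_widths()].
#' @param elapsed_hr hours between the two acquisitions (> 0).
#' @return closure rate, um/hr.
#' @export
closure_rate <- function(widths_t0, widths_t1, elapsed_hr) {
  if (elapsed_hr <= 0) stop("elapsed_hr must be > 0")
  (mean(widths_t0) - mean(widths_t1)) / elapsed_hr
}

#' Per-track motility statistics
#'
#' Total path length (sum of consecutive Euclidean steps), net displacement
#' (first to last position) and speed = total path / duration, where
#' duration is `(n - 1)` frame intervals. The raw, unsmoothed path is used.
#'
#' @param track data.frame with columns `frame`, `x`, `y` (um) for one cell.
#' @param frame_interval_min minutes per frame.
#' @return one-row data.frame: `total_path_um`, `net_um`, `duration_min`,
#'   `speed_um_min`.
#' @export
track_stats <- function(track, frame_interval_min) {
  if (nrow(track) < 2L) stop("a track needs at least 2 points")
  track <- track[order(track$frame), , drop = FALSE]
  steps <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  total <- sum(steps)
  net <- sqrt((track$x[nrow(track)] - track$x[1])^2 +
              (track$y[nrow(track)] - track$y[1])^2)
  duration <- (nrow(track) - 1L) * frame_interval_min
  data.frame(total_path_um = total, net_um = net, duration_min = duration,
             speed_um_min = total / duration)
}

#' Cohort speed over a set of tracks
#'
#' @param tracks a [track_table()].
#' @param subsample keep every k-th frame before measuring (k = 1: raw
#'   path). Subsampling reduces the upward speed bias caused by
#'   localization noise.
#' @return `list(per_track = data.frame(track_id, total_path_um, net_um,
#'   duration_min, speed_um_min), mean_speed_um_min = scalar)`.
#' @export
cohort_speed <- function(tracks, subsample = 1L) {
  stopifnot(inherits(tracks, "track_table"), subsample >= 1L)
  interval <- frame_interval(tracks)
  ids <- unique(tracks$track_id)
  if (!length(ids)) stop("track table is empty")
  per <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    if (subsample > 1L)
      tr <- tr[seq(1L, nrow(tr), by = subsample), , drop = FALSE]
    cbind(track_id = id, track_stats(tr, interval * subsample))
  }))
  list(per_track = per, mean_speed_um_min = mean(per$speed_um_min))
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour linking: at each frame, the globally closest
#' (active track, detection) pairs within `max_step_um` are matched first;
#' unmatched detections start new tracks, unmatched tracks end.
#'
#' @param detections list (one element per frame, in time order) of
#'   data.frames with columns `x`, `y` in um.
#' @param max_step_um gating distance: no link longer than this.
#' @param frame_interval_min minutes per frame for the output table.
#' @return a [track_table()].
#' @export
link_detections <- function(detections, max_step_um, frame_interval_min = 1) {
  stopifnot(max_step_um > 0)
  rows <- list()
  active <- data.frame(track_id = integer(0), x = numeric(0), y = numeric(0))
  next_id <- 1L
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    linked_det <- rep(FALSE, nrow(det))
    new_active <- active[0, ]
    if (nrow(active) && nrow(det)) {
      d <- outer(active$x, det$x, "-")^2 + outer(active$y, det$y, "-")^2
      repeat {
        i <- which.min(d)
        if (!length(i) || !is.finite(d[i]) || d[i] > max_step_um^2) break
        a <- (i - 1L) %% nrow(d) + 1L; j <- (i - 1L) %/% nrow(d) + 1L
        id <- active$track_id[a]
        rows[[length(rows) + 1L]] <- data.frame(track_id = id, frame = f,
                                                x = det$x[j], y = det$y[j])
        new_active <- rbind(new_active,
                            data.frame(track_id = id, x = det$x[j], y = det$y[j]))
        linked_det[j] <- TRUE
        d[a, ] <- Inf; d[, j] <- Inf
      }
    }
    for (j in which(!linked_det)) {
      rows[[length(rows) + 1L]] <- data.frame(track_id = next_id, frame = f,
                                              x = det$x[j], y = det$y[j])
      new_active <- rbind(new_active, data.frame(track_id = next_id,
                                                 x = det$x[j], y = det$y[j]))
      next_id <- next_id + 1L
    }
    active <- new_active
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(track_id = integer(0), frame = integer(0),
                        x = numeric(0), y = numeric(0))
  track_table(df, frame_interval_min)
}
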