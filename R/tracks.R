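# Track tables: time-ordered single-cell positions from time-lapse imaging.

#' Construct a track table
#'
#' A track table holds rows of `(track_id, frame, x, y)` with positions in
#' micrometers and a fixed frame interval in minutes. Frames within a track
#' must be strictly increasing; rows are stored sorted by track then frame.
#'
#' @param df data.frame with columns `track_id`, `frame`, `x`, `y`.
#' @param frame_interval_min minutes between consecutive frames (> 0).
#' @return a `track_table` (a data.frame with a `frame_interval_min` attribute).
#' @export
track_table <- function(df, frame_interval_min) {
  need <- c("track_id", "frame", "x", "y")
  if (!all(need %in% names(df)))
    stop("track table needs columns: ", paste(need, collapse = ", "))
  if (!is.numeric(frame_interval_min) || length(frame_interval_min) != 1L ||
      frame_interval_min <= 0)
    stop("frame_interval_min must be a single positive number")
  df <- as.data.frame(df)[need]
  df$frame <- as.integer(df$frame)
  if (nrow(df) > 0L) {
    if (anyDuplicated(df[c("track_id", "frame")]))
      stop("duplicate (track_id, frame) rows")
    df <- df[order(df$track_id, df$frame), , drop = FALSE]
    rownames(df) <- NULL
    mono <- tapply(df$frame, df$track_id, function(f) all(diff(f) > 0))
    if (!all(unlist(mono))) stop("frames within a track must strictly increase")
  }
  structure(df, frame_interval_min = as.numeric(frame_interval_min),
            class = c("track_table", "data.frame"))
}

#' Frame interval of a track table, minutes
#' @param x a `track_table`.
#' @export
frame_interval <- function(x) attr(x, "frame_interval_min")

#' Read a CSV track table
#'
#' @param path CSV with header `track_id,frame,x,y`; x/y are micrometers.
#' @param frame_interval_min minutes between frames.
#' @return a [track_table()].
#' @export
read_tracks <- function(path, frame_interval_min) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  track_table(df, frame_interval_min)
}

#' Write a track table to CSV (inverse of [read_tracks()])
#' @param tracks a [track_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
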