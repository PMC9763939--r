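#' Column dialect for spots tables
#'
#' Tracking exports name their columns differently between tool versions; a
#' dialect maps the roles this package needs onto the column names of a given
#' file. The defaults follow the common TrackMate "Spots" export dialect.
#'
#' @param track_id,frame,x,y,t,quality Column names holding, respectively, the
#'   track label, the 0-based frame index, the x and y positions (micrometers),
#'   the time stamp (seconds) and the detection quality score. `t` and
#'   `quality` may be absent from a file; they are then derived (time from the
#'   frame interval) or defaulted (quality 0).
#' @return A named list of class `spots_dialect`.
#' @export
spots_dialect <- function(track_id = "TRACK_ID", frame = "FRAME",
                          x = "POSITION_X", y = "POSITION_Y",
                          t = "POSITION_T", quality = "QUALITY") {
  structure(list(track_id = track_id, frame = frame, x = x, y = y,
                 t = t, quality = quality),
            class = "spots_dialect")
}

#' Acquisition information of a tracking experiment
#'
#' @param frame_interval Time between consecutive frames, seconds.
#' @param n_frames Expected number of frames of a complete track.
#' @param pixel_size Pixel size in micrometers per pixel, for image-derived
#'   tracks; `NA` for tracks read from tables already in micrometers.
#' @return A list of class `acquisition_info`.
#' @export
acquisition_info <- function(frame_interval = 10, n_frames = 60,
                             pixel_size = NA_real_) {
  stopifnot(is.numeric(frame_interval), frame_interval > 0,
            n_frames >= 2)
  structure(list(frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 pixel_size = pixel_size),
            class = "acquisition_info")
}

#' Times of the sampled frames
#'
#' Frame `k` (0-based) is acquired at `k * frame_interval`, so the last of 60
#' frames taken every 10 s falls at t = 590 s.
#'
#' @param n_frames Number of frames.
#' @param frame_interval Seconds between frames.
#' @return Numeric vector of length `n_frames`, starting at 0.
#' @export
frame_times <- function(n_frames, frame_interval = 10) {
  stopifnot(n_frames >= 1, frame_interval > 0)
  (seq_len(n_frames) - 1) * frame_interval
}

#' Number of frames sampled in a fixed acquisition window
#'
#' Sampling starts at t = 0 and covers the half-open window
#' `[0, window_duration)`: a 10-minute acquisition at one frame per 10 s
#' yields 60 frames (t = 0 ... 590 s).
#'
#' @param window_duration Window length in seconds.
#' @param frame_interval Seconds between frames.
#' @return Integer frame count.
#' @export
n_frames_in_window <- function(window_duration, frame_interval) {
  stopifnot(window_duration > 0, frame_interval > 0)
  as.integer(floor(window_duration / frame_interval - 1e-9)) + 1L
}

#' Construct a track set
#'
#' A track set is the package's container for trajectories: a spots data frame
#' (`track_id`, `frame`, `t`, `x`, `y`, `quality`; positions in micrometers)
#' plus acquisition metadata.
#'
#' @param spots Data frame with at least `track_id`, `frame`, `x`, `y`.
#' @param acquisition An [acquisition_info()] object.
#' @return An object of class `track_set`.
#' @export
track_set <- function(spots, acquisition = acquisition_info()) {
  stopifnot(is.data.frame(spots))
  required <- c("track_id", "frame", "x", "y")
  missing <- setdiff(required, names(spots))
  if (length(missing))
    stop("spots data frame lacks column(s): ", paste(missing, collapse = ", "))
  if (!"quality" %in% names(spots)) spots$quality <- rep(0, nrow(spots))
  if (!"t" %in% names(spots))
    spots$t <- spots$frame * acquisition$frame_interval
  if (anyNA(spots$t)) spots$t <- spots$frame * acquisition$frame_interval
  if (any(!is.finite(spots$x)) || any(!is.finite(spots$y)))
    stop("spot coordinates must be finite")
  if (any(spots$frame < 0)) stop("frame indices must be >= 0")
  spots <- spots[order(spots$track_id, spots$frame),
                 c("track_id", "frame", "t", "x", "y", "quality")]
  dup <- duplicated(spots[, c("track_id", "frame")])
  if (any(dup)) {
    bad <- spots[dup, , drop = FALSE][1, ]
    stop(sprintf("duplicate (track, frame) pair: track %s, frame %d",
                 format(bad$track_id), bad$frame))
  }
  rownames(spots) <- NULL
  structure(list(spots = spots, acquisition = acquisition),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  n_tr <- length(unique(x$spots$track_id))
  cat(sprintf("<track_set> %d track(s), %d spot(s), frame interval %g s\n",
              n_tr, nrow(x$spots), x$acquisition$frame_interval))
  invisible(x)
}

#' Split a track set into per-track data frames
#'
#' @param ts A `track_set`.
#' @return Named list of data frames, one per track, ordered by frame.
#' @export
tracks <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  split(ts$spots, ts$spots$track_id, drop = TRUE)
}

#' Number of tracks in a track set
#' @param ts A `track_set`.
#' @return Integer count.
#' @export
n_tracks <- function(ts) length(unique(ts$spots$track_id))

#' Read a spots table in a tracking-export dialect
#'
#' Reads a CSV "Spots" table, groups rows into tracks and sorts them by frame.
#' Secondary header rows (unit/label continuation lines that some exports place
#' under the header) are recognized by a non-numeric track-id field and
#' skipped.
#'
#' @param source Path or connection to a CSV file with a header row.
#' @param dialect A [spots_dialect()] mapping roles to column names.
#' @param acquisition An [acquisition_info()]; supplies the frame interval used
#'   when the file has no time column.
#' @return A [track_set()].
#' @export
read_spots_table <- function(source, dialect = spots_dialect(),
                             acquisition = acquisition_info()) {
  raw <- utils::read.csv(source, check.names = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("track_id", "frame", "x", "y")
  for (role in required) {
    if (!dialect[[role]] %in% names(raw))
      stop(sprintf("missing column: %s (expected as '%s')",
                   role, dialect[[role]]))
  }
  if (nrow(raw)) {
    id_num <- suppressWarnings(as.numeric(raw[[dialect$track_id]]))
    raw <- raw[!is.na(id_num), , drop = FALSE]
  }
  num <- function(role) suppressWarnings(as.numeric(raw[[dialect[[role]]]]))
  spots <- data.frame(
    track_id = as.integer(num("track_id")),
    frame = as.integer(num("frame")),
    x = num("x"),
    y = num("y")
  )
  if (!is.null(dialect$t) && dialect$t %in% names(raw)) {
    spots$t <- num("t")
  }
  if (!is.null(dialect$quality) && dialect$quality %in% names(raw)) {
    spots$quality <- num("quality")
  }
  if (nrow(spots) && (anyNA(spots$frame) || anyNA(spots$x) || anyNA(spots$y)))
    stop("non-numeric values in frame/x/y columns")
  track_set(spots, acquisition)
}

#' Keep only complete tracks
#'
#' Retains exactly the tracks whose spots cover frames
#' `0 .. expected_frames - 1` with no gaps, mirroring the practice of
#' analyzing only trajectories present at all 60 timepoints. A report of the
#' dropped tracks is attached as attribute `"filter_report"`.
#'
#' @param ts A `track_set`.
#' @param expected_frames Number of frames a complete track must have; defaults
#'   to the acquisition's `n_frames`.
#' @return A filtered `track_set` (possibly empty) with a `filter_report`
#'   attribute: a list with `n_kept`, `n_dropped` and `dropped_ids`.
#' @export
filter_complete <- function(ts, expected_frames = NULL) {
  stopifnot(inherits(ts, "track_set"))
  if (is.null(expected_frames)) expected_frames <- ts$acquisition$n_frames
  stopifnot(expected_frames >= 2)
  want <- 0:(expected_frames - 1)
  by_track <- split(ts$spots$frame, ts$spots$track_id)
  complete <- vapply(by_track, function(fr) {
    length(fr) == expected_frames && all(sort(fr) == want)
  }, logical(1))
  keep_ids <- names(by_track)[complete]
  out <- ts
  out$spots <- ts$spots[as.character(ts$spots$track_id) %in% keep_ids, ,
                        drop = FALSE]
  rownames(out$spots) <- NULL
  attr(out, "filter_report") <- list(
    n_kept = sum(complete),
    n_dropped = sum(!complete),
    dropped_ids = names(by_track)[!complete]
  )
  out
}

#' Write a track set as a spots table
#'
#' Emits a CSV readable by [read_spots_table()]; the round trip preserves
#' track ids, frames, coordinates and quality to 6 decimal places.
#'
#' @param ts A `track_set`.
#' @param sink Path or writable connection.
#' @param dialect Column dialect to write.
#' @export
write_tracks_table <- function(ts, sink, dialect = spots_dialect()) {
  stopifnot(inherits(ts, "track_set"))
  out <- data.frame(
    a = ts$spots$track_id,
    b = ts$spots$frame,
    c = sprintf("%.6f", ts$spots$x),
    d = sprintf("%.6f", ts$spots$y),
    e = sprintf("%.6f", ts$spots$t),
    f = sprintf("%.6f", ts$spots$quality)
  )
  names(out) <- c(dialect$track_id, dialect$frame, dialect$x, dialect$y,
                  dialect$t, dialect$quality)
  utils::write.csv(out, sink, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
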