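#' Frame bookkeeping at 25 Hz
#'
#' Annotation timelines run at the video frame rate of 25 Hz, i.e. one
#' label per 40 ms. `frames_for_duration` converts a duration in seconds
#' to the frame count, rounding to the nearest frame.
#'
#' @param duration duration in seconds (>= 0).
#' @return Integer frame count, `round(duration * 25)`.
#' @examples
#' frames_for_duration(60)      # one minute -> 1500 frames
#' frames_for_duration(421.04)  # 10526 frames
#' @export
frames_for_duration <- function(duration) {
  if (!is.numeric(duration) || any(!is.finite(duration)) || any(duration < 0))
    stop_input("duration must be finite and >= 0")
  as.integer(round(duration * 25))
}

#' Pick the gaze point for one video frame
#'
#' Frame `f` covers the half-open window `[40 f, 40 (f + 1))` ms. Among the
#' valid samples in that window, the one whose timestamp is nearest the
#' frame midpoint (`40 f + 20` ms) is chosen; an exact tie is broken
#' toward the earlier sample, so the choice is deterministic. With no
#' valid sample in the window the frame has missing gaze.
#'
#' @param samples data.frame with columns `timestamp_ms`, `x_px`, `y_px`,
#'   `valid` (logical), sorted by timestamp.
#' @param frame_index zero-based frame index.
#' @return Named numeric `c(x, y)`, or `NULL` when the window holds no
#'   valid sample.
#' @export
gaze_for_frame <- function(samples, frame_index) {
  t0 <- frame_index * 40
  in_win <- samples$timestamp_ms >= t0 & samples$timestamp_ms < t0 + 40 &
    samples$valid
  if (!any(in_win)) return(NULL)
  cand <- samples[in_win, , drop = FALSE]
  d <- abs(cand$timestamp_ms - (t0 + 20))
  i <- which(d == min(d))[1L]  # candidates are time-ordered; first = earlier
  c(x = cand$x_px[i], y = cand$y_px[i])
}

# vectorized frame -> gaze point table for all frames 0..n_frames-1;
# returns data.frame(frame, x, y) with one row per frame that has gaze
.gaze_by_frame <- function(samples, n_frames) {
  s <- samples[samples$valid, , drop = FALSE]
  frame <- floor(s$timestamp_ms / 40)
  ok <- frame >= 0 & frame < n_frames
  s <- s[ok, , drop = FALSE]; frame <- frame[ok]
  if (nrow(s) == 0L)
    return(data.frame(frame = integer(), x = numeric(), y = numeric()))
  d <- abs(s$timestamp_ms - (frame * 40 + 20))
  # order by frame, then distance to midpoint, then timestamp (tie -> earlier)
  o <- order(frame, d, s$timestamp_ms)
  first <- !duplicated(frame[o])
  sel <- o[first]
  data.frame(frame = as.integer(frame[sel]), x = s$x_px[sel], y = s$y_px[sel])
}

#' Test whether a gaze point falls inside an AOI
#'
#' Rectangle: inside iff `|x - cx| <= w/2` and `|y - cy| <= h/2`; oval:
#' inside iff `((x-cx)/(w/2))^2 + ((y-cy)/(h/2))^2 <= 1`. Both boundaries
#' are inclusive: manual annotators draw the face area with a small
#' margin, so an edge hit counts as a hit.
#'
#' @param point numeric `c(x, y)` in pixels.
#' @param aoi an [aoi] object (or a one-row slice of a [build_aois()]
#'   table).
#' @return Logical.
#' @export
hit_test <- function(point, aoi) {
  dx <- (point[[1L]] - aoi$center_x) / (aoi$width / 2)
  dy <- (point[[2L]] - aoi$center_y) / (aoi$height / 2)
  if (identical(aoi$shape, "oval")) dx^2 + dy^2 <= 1
  else abs(dx) <= 1 && abs(dy) <= 1
}

# vectorized hit test: point against every row of an AOI table
.hits <- function(x, y, aois) {
  dx <- (x - aois$center_x) / (aois$width / 2)
  dy <- (y - aois$center_y) / (aois$height / 2)
  ifelse(aois$shape == "oval", dx^2 + dy^2 <= 1, abs(dx) <= 1 & abs(dy) <= 1)
}

#' Annotate a single-class (any-face) timeline
#'
#' Produces the binary per-40-ms spreadsheet: a frame is labelled 1 when
#' its gaze point falls inside at least one face AOI of that frame, and 0
#' otherwise — including frames with no AOI and frames with missing or
#' invalid gaze (the timeline has no third state; missingness is counted
#' separately in the `n_missing_gaze` attribute).
#'
#' @param samples gaze sample data.frame (see [read_gaze()]).
#' @param aois AOI table from [build_aois()] (column `frame` indexes
#'   frames).
#' @param n_frames number of frames in the timeline.
#' @return Integer vector of 0/1 labels of length `n_frames`, with
#'   attribute `n_missing_gaze`.
#' @export
annotate_single_class <- function(samples, aois, n_frames) {
  g <- .gaze_by_frame(samples, n_frames)
  labels <- integer(n_frames)
  if (nrow(g) > 0L && nrow(aois) > 0L) {
    idx <- split(seq_len(nrow(aois)), aois$frame)
    for (k in seq_len(nrow(g))) {
      rows <- idx[[as.character(g$frame[k])]]
      if (!is.null(rows) &&
          any(.hits(g$x[k], g$y[k], aois[rows, , drop = FALSE])))
        labels[g$frame[k] + 1L] <- 1L
    }
  }
  structure(labels, n_missing_gaze = n_frames - nrow(g))
}

#' Annotate a multiple-class (per-identity) timeline
#'
#' Like [annotate_single_class()], but every AOI carries an identity label
#' and the frame is labelled with the identity of the hit face. When the
#' gaze point falls inside several overlapping AOIs, the AOI whose center
#' is nearest the gaze point wins (stable under margin changes, unlike a
#' smallest-area rule). Frames with no hit are labelled `"0"`.
#'
#' @inheritParams annotate_single_class
#' @return Character vector of identity labels (or `"0"`) of length
#'   `n_frames`, with attribute `n_missing_gaze`.
#' @export
annotate_multi_class <- function(samples, aois, n_frames) {
  if (nrow(aois) > 0L && any(is.na(aois$identity)))
    stop_input("annotate_multi_class: every AOI must carry an identity")
  g <- .gaze_by_frame(samples, n_frames)
  labels <- rep("0", n_frames)
  if (nrow(g) > 0L && nrow(aois) > 0L) {
    idx <- split(seq_len(nrow(aois)), aois$frame)
    for (k in seq_len(nrow(g))) {
      rows <- idx[[as.character(g$frame[k])]]
      if (is.null(rows)) next
      a <- aois[rows, , drop = FALSE]
      hit <- .hits(g$x[k], g$y[k], a)
      if (any(hit)) {
        a <- a[hit, , drop = FALSE]
        d2 <- (g$x[k] - a$center_x)^2 + (g$y[k] - a$center_y)^2
        labels[g$frame[k] + 1L] <- a$identity[which.min(d2)]
      }
    }
  }
  structure(labels, n_missing_gaze = n_frames - nrow(g))
}

#' Cumulative face-gaze duration of a timeline
#'
#' The number of non-zero frames times the 40-ms frame period. For a
#' multiple-class timeline an `identity` restricts the count to one
#' person's face.
#'
#' @param timeline label vector (0/1 or identity labels with `"0"` = no
#'   face).
#' @param identity optional identity label to filter on.
#' @return Duration in seconds.
#' @examples
#' face_gaze_duration(c(1, 1, 0, 1))  # 0.12 s
#' @export
face_gaze_duration <- function(timeline, identity = NULL) {
  lab <- as.character(timeline)
  n <- if (is.null(identity)) sum(lab != "0") else sum(lab == as.character(identity))
  n * 0.04
}
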