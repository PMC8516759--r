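#' Head landmark names
#'
#' The five head landmarks used to locate a face: the nose, both eyes and
#' both ears. A pose detector reports a pixel position and a confidence for
#' each; a landmark the detector did not find carries confidence 0.
#'
#' @format Character vector of length five.
#' @export
HEAD_LANDMARKS <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear")

# short column prefixes used in the keypoint CSV dialect
.LANDMARK_PREFIX <- c(nose = "nose", left_eye = "leye", right_eye = "reye",
                      left_ear = "lear", right_ear = "rear")

#' Construct a set of head keypoints for one person in one frame
#'
#' @param nose,left_eye,right_eye,left_ear,right_ear numeric vectors
#'   `c(x, y)` or `c(x, y, confidence)` in pixel coordinates (origin
#'   top-left, y increasing downward). `NULL` means the landmark was not
#'   detected (confidence 0). When a confidence is omitted it defaults to 1.
#' @param frame,person zero-based frame and person indices.
#' @return An object of class `head_keypoints`: a 5 x 3 matrix of
#'   `x`, `y`, `conf` rows named after [HEAD_LANDMARKS], with `frame` and
#'   `person` attributes.
#' @examples
#' kp <- head_keypoints(nose = c(100, 60), left_eye = c(90, 50),
#'                      right_eye = c(110, 50))
#' classify_orientation(kp)
#' @export
head_keypoints <- function(nose = NULL, left_eye = NULL, right_eye = NULL,
                           left_ear = NULL, right_ear = NULL,
                           frame = 0L, person = 0L) {
  pts <- list(nose, left_eye, right_eye, left_ear, right_ear)
  m <- matrix(NA_real_, nrow = 5L, ncol = 3L,
              dimnames = list(HEAD_LANDMARKS, c("x", "y", "conf")))
  for (i in seq_len(5L)) {
    p <- pts[[i]]
    if (is.null(p)) {
      m[i, ] <- c(NA_real_, NA_real_, 0)
    } else {
      if (!is.numeric(p) || !(length(p) %in% c(2L, 3L)))
        stop_input("landmark '", HEAD_LANDMARKS[i],
                   "' must be c(x, y) or c(x, y, confidence)")
      m[i, ] <- c(p[1L], p[2L], if (length(p) == 3L) p[3L] else 1)
    }
  }
  structure(m, frame = as.integer(frame), person = as.integer(person),
            class = "head_keypoints")
}

#' Which landmarks count as visible
#'
#' A landmark is visible when its detector confidence reaches
#' `conf_threshold` and its coordinates are finite. Pose detectors report a
#' confidence per landmark; the threshold (default 0.1) separates genuine
#' detections from placeholder zeros.
#'
#' @param kp a [head_keypoints] object.
#' @param conf_threshold minimum confidence for a landmark to count.
#' @return Named logical vector over [HEAD_LANDMARKS].
#' @export
visible_points <- function(kp, conf_threshold = 0.1) {
  stopifnot(inherits(kp, "head_keypoints"))
  v <- kp[, "conf"] >= conf_threshold &
    is.finite(kp[, "x"]) & is.finite(kp[, "y"])
  stats::setNames(as.logical(v), HEAD_LANDMARKS)
}

# one wide CSV row (named list / 1-row data.frame) -> head_keypoints
keypoints_from_row <- function(row) {
  args <- lapply(.LANDMARK_PREFIX, function(p) {
    x <- row[[paste0(p, "_x")]]
    y <- row[[paste0(p, "_y")]]
    cc <- row[[paste0(p, "_c")]]
    if (is.null(cc) || is.na(cc)) cc <- 0
    if (is.na(x) || is.na(y)) return(NULL)
    c(x, y, cc)
  })
  names(args) <- HEAD_LANDMARKS
  do.call(head_keypoints,
          c(args, list(frame = row[["frame"]], person = row[["person"]])))
}

#' @export
print.head_keypoints <- function(x, ...) {
  cat(sprintf("<head_keypoints> frame %d, person %d\n",
              attr(x, "frame"), attr(x, "person")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}
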