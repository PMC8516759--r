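#' Area-of-interest construction parameters
#'
#' Parameters controlling how a face area-of-interest (AOI) is derived from
#' head keypoints. The AOI width is the largest pairwise distance between
#' the visible landmarks times the margin scale; the height is that width
#' times the aspect ratio (height/width) times the margin. Frontal faces
#' (all five landmarks visible) and profile faces (two to four visible) use
#' separate aspect ratios, margins and vertical center offsets, since a
#' profile exposes a narrower span of landmarks for the same head.
#'
#' The shipped defaults (frontal aspect 1.4, profile aspect 1.2, margins
#' 1.2, offsets 0) are configurable placeholders: the appropriate values
#' depend on the recording and are usually calibrated against a sample of
#' manual annotations.
#'
#' @param aspect_frontal,aspect_profile height/width ratio (> 0).
#' @param margin_frontal,margin_profile scale applied to both width and
#'   height (>= 1 guarantees the box covers the landmarks).
#' @param offset_frontal,offset_profile signed vertical center shift as a
#'   fraction of the AOI height, in [-1, 1]; positive moves the center
#'   down-screen.
#' @param shape `"rectangle"` (default) or `"oval"`; the oval is the
#'   axis-aligned ellipse inscribed in the same bounding box.
#' @param conf_threshold landmark visibility threshold, see
#'   [visible_points()].
#' @return An object of class `aoi_params` (a validated list).
#' @export
aoi_params <- function(aspect_frontal = 1.4, aspect_profile = 1.2,
                       margin_frontal = 1.2, margin_profile = 1.2,
                       offset_frontal = 0, offset_profile = 0,
                       shape = c("rectangle", "oval"),
                       conf_threshold = 0.1) {
  shape <- match.arg(shape)
  p <- list(aspect_frontal = aspect_frontal, aspect_profile = aspect_profile,
            margin_frontal = margin_frontal, margin_profile = margin_profile,
            offset_frontal = offset_frontal, offset_profile = offset_profile,
            shape = shape, conf_threshold = conf_threshold)
  num <- vapply(p[1:6], function(x) is.numeric(x) && length(x) == 1L &&
                  is.finite(x), logical(1L))
  if (!all(num))
    stop_config("all aoi_params ratios, margins and offsets must be single finite numbers")
  if (aspect_frontal <= 0 || aspect_profile <= 0)
    stop_config("aspect ratios must be > 0")
  if (margin_frontal <= 0 || margin_profile <= 0)
    stop_config("margin scales must be > 0")
  if (abs(offset_frontal) > 1 || abs(offset_profile) > 1)
    stop_config("center offsets must lie in [-1, 1]")
  structure(p, class = "aoi_params")
}

#' Classify face orientation from landmark visibility
#'
#' A head with all five landmarks visible is a frontal face; with two to
#' four visible (typically because the far-side ear and eye are occluded by
#' head turning) it is a profile face; with at most one visible landmark
#' the head is undetected and yields no AOI.
#'
#' @inheritParams visible_points
#' @return One of `"frontal"`, `"profile"`, `"undetected"`.
#' @export
classify_orientation <- function(kp, conf_threshold = 0.1) {
  n <- sum(visible_points(kp, conf_threshold))
  if (n == 5L) "frontal" else if (n >= 2L) "profile" else "undetected"
}

#' Head width from visible landmarks
#'
#' The AOI width in pixels: the largest Euclidean distance over all pairs
#' of visible landmarks.
#'
#' @inheritParams visible_points
#' @return Width in pixels.
#' @export
head_width <- function(kp, conf_threshold = 0.1) {
  v <- visible_points(kp, conf_threshold)
  if (sum(v) < 2L)
    stop_input("head undetected: fewer than 2 visible landmarks")
  xy <- unclass(kp)[v, c("x", "y"), drop = FALSE]
  max(stats::dist(xy))
}

#' Build a face area-of-interest from head keypoints
#'
#' Implements the keypoint-to-AOI rule: classify the face as frontal or
#' profile from landmark visibility, take the largest pairwise landmark
#' distance as the base width, scale width by the margin and height by
#' aspect ratio times margin, and center the box on the midpoint of the
#' bounding box of the visible landmarks, shifted vertically by the
#' configured offset fraction of the height. Midpoint centering (rather
#' than the landmark centroid) guarantees the box covers every visible
#' landmark whenever margin >= 1 and aspect ratio >= 1. An undetected
#' head (fewer than two visible landmarks) yields `NULL`, never an
#' error.
#'
#' @inheritParams visible_points
#' @param params an [aoi_params] object.
#' @param identity optional identity label to tag the AOI with.
#' @return An object of class `aoi` (list with `frame`, `person`, `shape`,
#'   `center_x`, `center_y`, `width`, `height`, `identity`), or `NULL`.
#' @examples
#' kp <- head_keypoints(nose = c(0, 0), left_ear = c(30, 0))
#' build_aoi(kp, aoi_params(aspect_profile = 1, margin_profile = 1))
#' @export
build_aoi <- function(kp, params = aoi_params(), identity = NA_character_) {
  stopifnot(inherits(params, "aoi_params"))
  orient <- classify_orientation(kp, params$conf_threshold)
  if (orient == "undetected") return(NULL)
  v <- visible_points(kp, params$conf_threshold)
  w0 <- head_width(kp, params$conf_threshold)
  if (orient == "frontal") {
    margin <- params$margin_frontal; aspect <- params$aspect_frontal
    offset <- params$offset_frontal
  } else {
    margin <- params$margin_profile; aspect <- params$aspect_profile
    offset <- params$offset_profile
  }
  width <- w0 * margin
  height <- w0 * aspect * margin
  xy <- unclass(kp)[v, c("x", "y"), drop = FALSE]
  structure(list(frame = attr(kp, "frame"), person = attr(kp, "person"),
                 shape = params$shape,
                 center_x = (min(xy[, "x"]) + max(xy[, "x"])) / 2,
                 center_y = (min(xy[, "y"]) + max(xy[, "y"])) / 2 +
                   offset * height,
                 width = width, height = height,
                 orientation = orient,
                 identity = identity),
            class = "aoi")
}

#' Build AOIs for every detected head in a keypoint table
#'
#' Applies [build_aoi()] to each row of a wide keypoint table (one row per
#' person per frame, the dialect read by [read_keypoints()]); undetected
#' heads are dropped.
#'
#' @param keypoints data.frame in the wide keypoint dialect.
#' @param params an [aoi_params] object.
#' @return data.frame with one row per AOI: `frame`, `person`, `shape`,
#'   `center_x`, `center_y`, `width`, `height`, `orientation`, `identity`.
#' @export
build_aois <- function(keypoints, params = aoi_params()) {
  n <- nrow(keypoints)
  empty <- data.frame(frame = integer(), person = integer(),
                      shape = character(), center_x = numeric(),
                      center_y = numeric(), width = numeric(),
                      height = numeric(), orientation = character(),
                      identity = character(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  pref <- unname(.LANDMARK_PREFIX)
  X <- sapply(pref, function(p) as.numeric(keypoints[[paste0(p, "_x")]]))
  Y <- sapply(pref, function(p) as.numeric(keypoints[[paste0(p, "_y")]]))
  C <- sapply(pref, function(p) {
    cc <- as.numeric(keypoints[[paste0(p, "_c")]])
    cc[is.na(cc)] <- 0
    cc
  })
  X <- matrix(X, nrow = n); Y <- matrix(Y, nrow = n); C <- matrix(C, nrow = n)
  vis <- C >= params$conf_threshold & is.finite(X) & is.finite(Y)
  nvis <- rowSums(vis)
  keep <- nvis >= 2L
  if (!any(keep)) return(empty)
  # largest pairwise distance over the 10 landmark pairs, per row
  w0 <- rep(-Inf, n)
  for (i in 1:4) for (j in (i + 1):5) {
    ok <- vis[, i] & vis[, j]
    d <- sqrt((X[, i] - X[, j])^2 + (Y[, i] - Y[, j])^2)
    w0 <- pmax(w0, ifelse(ok, d, -Inf))
  }
  Xlo <- X; Xlo[!vis] <- Inf; Xhi <- X; Xhi[!vis] <- -Inf
  Ylo <- Y; Ylo[!vis] <- Inf; Yhi <- Y; Yhi[!vis] <- -Inf
  cx <- (apply(Xlo, 1L, min) + apply(Xhi, 1L, max)) / 2
  cy <- (apply(Ylo, 1L, min) + apply(Yhi, 1L, max)) / 2
  frontal <- nvis == 5L
  margin <- ifelse(frontal, params$margin_frontal, params$margin_profile)
  aspect <- ifelse(frontal, params$aspect_frontal, params$aspect_profile)
  offset <- ifelse(frontal, params$offset_frontal, params$offset_profile)
  width <- w0 * margin
  height <- w0 * aspect * margin
  out <- data.frame(
    frame = as.integer(keypoints$frame),
    person = as.integer(keypoints$person),
    shape = params$shape,
    center_x = cx,
    center_y = cy + offset * height,
    width = width,
    height = height,
    orientation = ifelse(frontal, "frontal", "profile"),
    identity = NA_character_,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.aoi <- function(x, ...) {
  cat(sprintf("<aoi> frame %s person %s: %s %.1f x %.1f at (%.1f, %.1f)%s\n",
              x$frame, x$person, x$shape, x$width, x$height,
              x$center_x, x$center_y,
              if (is.na(x$identity)) "" else paste0(" [", x$identity, "]")))
  invisible(x)
}
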