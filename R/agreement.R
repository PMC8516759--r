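#' Cohen's kappa between two annotation timelines
#'
#' Chance-corrected frame-wise agreement, `(p_o - p_e) / (1 - p_e)`, where
#' `p_o` is the observed proportion of agreeing frames and `p_e` the
#' agreement expected from the two raters' marginal label frequencies.
#' Defined for binary and multi-label timelines (plain, unweighted kappa
#' over the label set including the no-face label 0). In the degenerate
#' case `p_e = 1` — both raters constant and identical — kappa is returned
#' as 1 with a warning, since the raters agree everywhere.
#'
#' @param a,b label vectors of equal length.
#' @return Kappa in [-1, 1].
#' @examples
#' cohens_kappa(c(1, 1, 1, 0), c(1, 1, 0, 0))  # 0.5
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b))
    stop_input("timelines differ in length: ", length(a), " vs ", length(b))
  if (length(a) == 0L) stop_input("timelines are empty")
  a <- as.character(a); b <- as.character(b)
  labs <- sort(unique(c(a, b)))
  tab <- table(factor(a, levels = labs), factor(b, levels = labs))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (isTRUE(all.equal(p_e, 1))) {
    warning("both raters are constant and identical; kappa = 1 by convention")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Frame-by-frame accuracy between two timelines
#'
#' The percentage of frames on which the two annotations carry the same
#' label ("true positives" when one rater is treated as ground truth).
#'
#' @param a,b label vectors of equal length.
#' @return Percent in [0, 100].
#' @export
frame_accuracy <- function(a, b) {
  if (length(a) != length(b))
    stop_input("timelines differ in length: ", length(a), " vs ", length(b))
  if (length(a) == 0L) stop_input("timelines are empty")
  100 * mean(as.character(a) == as.character(b))
}

#' Difference in face-gaze totals between two timelines
#'
#' The signed difference in cumulative face-gaze duration, `a - b`, and
#' its absolute value normalized by the total video duration in percent.
#' Two conventions are available: `"net"` (default) takes the difference
#' of the two totals, so over- and under-identification in different
#' frames cancel; `"framewise"` sums the mismatched frames (0.04 s each),
#' so they do not.
#'
#' @param a,b label vectors of equal length (0 = no face).
#' @param convention `"net"` or `"framewise"`.
#' @return List with `delta_s` (signed seconds; `NA` sign under the
#'   framewise convention is avoided by keeping the net sign),
#'   `normalized_pct`, `duration_a_s`, `duration_b_s`, `total_s`.
#' @examples
#' a <- c(rep(1, 761), rep(0, 735))   # 30.44 s of face-gaze
#' b <- c(rep(1, 765), rep(0, 731))   # 30.60 s
#' normalized_difference(a, b)$normalized_pct
#' @export
normalized_difference <- function(a, b, convention = c("net", "framewise")) {
  convention <- match.arg(convention)
  if (length(a) != length(b))
    stop_input("timelines differ in length: ", length(a), " vs ", length(b))
  if (length(a) == 0L) stop_input("timelines are empty")
  da <- face_gaze_duration(a)
  db <- face_gaze_duration(b)
  total <- length(a) * 0.04
  delta <- da - db
  mag <- if (convention == "net") abs(delta)
         else sum(as.character(a) != as.character(b)) * 0.04
  list(delta_s = delta, normalized_pct = 100 * mag / total,
       duration_a_s = da, duration_b_s = db, total_s = total)
}

#' Identity confusion matrix between manual and algorithm timelines
#'
#' Cross-tabulates the per-frame identity labels of a manual annotation
#' (rows) against an automated one (columns) over the full label set
#' including 0 (no face). The Re-ID accuracy is the percentage of frames
#' on the diagonal.
#'
#' @param manual,algorithm multi-class label vectors of equal length.
#' @return Object of class `reid_confusion`: list with `labels`, `counts`
#'   (matrix, manual rows x algorithm columns) and `accuracy_pct`.
#' @export
confusion_matrix <- function(manual, algorithm) {
  if (length(manual) != length(algorithm))
    stop_input("timelines differ in length: ", length(manual), " vs ",
               length(algorithm))
  if (length(manual) == 0L) stop_input("timelines are empty")
  m <- as.character(manual); a <- as.character(algorithm)
  ids <- sort(setdiff(unique(c(m, a)), "0"))
  labs <- c("0", ids)
  counts <- table(manual = factor(m, levels = labs),
                  algorithm = factor(a, levels = labs))
  counts <- unclass(counts)
  structure(list(labels = labs, counts = counts,
                 accuracy_pct = 100 * sum(diag(counts)) / length(m)),
            class = "reid_confusion")
}

#' @export
print.reid_confusion <- function(x, ...) {
  cat("<reid_confusion> manual rows x algorithm columns\n")
  print(x$counts)
  cat(sprintf("Re-ID accuracy: %.2f%%\n", x$accuracy_pct))
  invisible(x)
}

#' Full agreement report between two timelines
#'
#' Bundles the per-video evaluation: Cohen's kappa, frame-by-frame
#' accuracy, both face-gaze totals, the signed difference and the
#' normalized absolute difference.
#'
#' @inheritParams normalized_difference
#' @return Object of class `agreement_report`: list with `kappa`,
#'   `accuracy_pct`, `duration_a_s`, `duration_b_s`, `delta_s`,
#'   `normalized_delta_pct`, `n_frames`, `convention`.
#' @export
agreement_report <- function(a, b, convention = c("net", "framewise")) {
  convention <- match.arg(convention)
  nd <- normalized_difference(a, b, convention)
  structure(list(kappa = cohens_kappa(a, b),
                 accuracy_pct = frame_accuracy(a, b),
                 duration_a_s = nd$duration_a_s,
                 duration_b_s = nd$duration_b_s,
                 delta_s = nd$delta_s,
                 normalized_delta_pct = nd$normalized_pct,
                 n_frames = length(a),
                 convention = convention),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<agreement_report> %d frames (%.2f s)\n",
    "  face-gaze: %.2f s vs %.2f s  (delta %+.2f s, normalized %.2f%%, %s)\n",
    "  accuracy %.2f%%, Cohen's kappa %.3f\n"),
    x$n_frames, x$n_frames * 0.04, x$duration_a_s, x$duration_b_s,
    x$delta_s, x$normalized_delta_pct, x$convention, x$accuracy_pct, x$kappa))
  invisible(x)
}
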