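# All dialects are UTF-8, "." decimal separator, comma-separated CSV
# except the tab-separated gaze export. Writers and readers round-trip
# losslessly; readers validate headers and report offending line numbers.

# full-precision numeric formatting so write -> read is lossless
.fmt_num <- function(x, na = "") {
  out <- sprintf("%.17g", as.numeric(x))
  out[is.na(x)] <- na
  out
}

.check_header <- function(got, want, path) {
  if (!identical(as.character(got), want))
    stop_format("'", path, "': expected header '",
                paste(want, collapse = ","), "', got '",
                paste(got, collapse = ","), "'")
}

GAZE_COLUMNS <- c("timestamp_ms", "x_px", "y_px", "valid")

#' Read and write gaze samples
#'
#' Tab-separated export with header
#' `timestamp_ms\tx_px\ty_px\tvalid`, one raw gaze sample per row
#' (screen pixel coordinates, no fixation or attention filtering).
#' Timestamps must be non-decreasing; `valid` is 0/1. An invalid sample
#' keeps its row so that missingness can be counted.
#'
#' @param path file path.
#' @param samples data.frame with the four gaze columns.
#' @return `read_gaze`: data.frame with columns `timestamp_ms`, `x_px`,
#'   `y_px`, `valid` (logical).
#' @export
read_gaze <- function(path) {
  if (!file.exists(path)) stop_format("gaze file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  .check_header(hdr, GAZE_COLUMNS, path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  bad <- which(!is.finite(d$timestamp_ms))
  if (length(bad))
    stop_format("'", path, "': non-numeric timestamp at line ", bad[1L] + 1L)
  back <- which(diff(d$timestamp_ms) < 0)
  if (length(back))
    stop_format("'", path, "': timestamp decreases at line ", back[1L] + 2L)
  d$valid <- as.logical(d$valid)
  d
}

#' @rdname read_gaze
#' @export
write_gaze <- function(samples, path) {
  out <- samples[, GAZE_COLUMNS]
  out$timestamp_ms <- .fmt_num(out$timestamp_ms)
  out$x_px <- .fmt_num(out$x_px)
  out$y_px <- .fmt_num(out$y_px)
  out$valid <- as.integer(out$valid)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

KEYPOINT_COLUMNS <- c("frame", "person",
                      as.vector(t(outer(c("nose", "leye", "reye", "lear", "rear"),
                                        c("_x", "_y", "_c"), paste0))))

#' Read and write head-keypoint tables
#'
#' CSV with one row per detected person per frame and header
#' `frame,person,nose_x,nose_y,nose_c,leye_x,...,rear_c`: pixel
#' coordinates and detector confidence for the five head landmarks. A
#' missing landmark is encoded as empty coordinate fields with
#' confidence 0.
#'
#' @param path file path.
#' @param keypoints data.frame in the wide keypoint dialect.
#' @return `read_keypoints`: the keypoint data.frame.
#' @export
read_keypoints <- function(path) {
  if (!file.exists(path)) stop_format("keypoint file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  .check_header(hdr, KEYPOINT_COLUMNS, path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in grep("_c$", KEYPOINT_COLUMNS, value = TRUE))
    d[[col]][is.na(d[[col]])] <- 0
  bad <- which(!is.finite(d$frame) | d$frame < 0 |
                 !is.finite(d$person) | d$person < 0)
  if (length(bad))
    stop_format("'", path, "': bad frame/person index at line ", bad[1L] + 1L)
  d
}

#' @rdname read_keypoints
#' @export
write_keypoints <- function(keypoints, path) {
  out <- keypoints[, KEYPOINT_COLUMNS]
  for (col in KEYPOINT_COLUMNS[-(1:2)]) out[[col]] <- .fmt_num(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write per-frame embedding tables and galleries
#'
#' Per-frame embeddings: CSV `frame,person,e0,...,e<d-1>`, one row per
#' detected person per frame. Gallery: CSV `label,e0,...,e<d-1>`, one
#' labelled entry per row. The embedding dimensionality is fixed across
#' a file (conventionally 128); a row with the wrong number of fields is
#' a format error naming the line.
#'
#' @param path file path.
#' @param embeddings data.frame `frame,person,e0..`.
#' @param gallery a [reid_gallery].
#' @return `read_embeddings`: the embedding data.frame; `read_gallery`: a
#'   [reid_gallery].
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop_format("embedding file not found: ", path)
  d <- .read_embedding_csv(path, c("frame", "person"))
  d$frame <- as.integer(d$frame)
  d$person <- as.integer(d$person)
  d
}

.read_embedding_csv <- function(path, lead_cols) {
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  ndim <- length(hdr) - length(lead_cols)
  if (ndim < 1L)
    stop_format("'", path, "': no embedding columns in header")
  .check_header(hdr, c(lead_cols, paste0("e", seq_len(ndim) - 1L)), path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  bad <- which(nf != length(hdr))
  if (length(bad))
    stop_format("'", path, "': expected ", length(hdr), " fields but found ",
                nf[bad[1L]], " at line ", bad[1L])
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  emat <- as.matrix(d[, -seq_along(lead_cols), drop = FALSE])
  if (nrow(d) > 0L && any(!is.finite(emat)))
    stop_format("'", path, "': non-finite embedding component at line ",
                which(rowSums(!is.finite(emat)) > 0)[1L] + 1L)
  d
}

#' @rdname read_embeddings
#' @export
write_embeddings <- function(embeddings, path) {
  out <- embeddings
  for (col in grep("^e[0-9]+$", names(out), value = TRUE))
    out[[col]] <- .fmt_num(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_embeddings
#' @export
read_gallery <- function(path) {
  if (!file.exists(path)) stop_format("gallery file not found: ", path)
  d <- .read_embedding_csv(path, "label")
  if (nrow(d) == 0L) stop_format("'", path, "': gallery has no entries")
  reid_gallery(as.matrix(d[, -1L, drop = FALSE]), as.character(d$label))
}

#' @rdname read_embeddings
#' @export
write_gallery <- function(gallery, path) {
  stopifnot(inherits(gallery, "reid_gallery"))
  d <- data.frame(label = gallery$labels, stringsAsFactors = FALSE)
  emb <- apply(gallery$embeddings, 2L, .fmt_num)
  if (is.null(dim(emb))) emb <- matrix(emb, nrow = length(gallery$labels))
  colnames(emb) <- paste0("e", seq_len(ncol(gallery$embeddings)) - 1L)
  utils::write.csv(cbind(d, as.data.frame(emb, stringsAsFactors = FALSE)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write annotation timelines
#'
#' CSV `frame,label`, one row per 40-ms frame, frames consecutive from
#' 0. Labels are `0`/`1` for a single-class (any-face) timeline, or
#' identity strings with `0` meaning no face for a multiple-class one.
#' The round trip is bit-exact.
#'
#' @param path file path.
#' @param timeline label vector.
#' @return `read_timeline`: integer vector for a 0/1 timeline, character
#'   vector otherwise.
#' @export
read_timeline <- function(path) {
  if (!file.exists(path)) stop_format("timeline file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  .check_header(hdr, c("frame", "label"), path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c("integer", "character"))
  if (nrow(d) > 0L && !identical(d$frame, 0:(nrow(d) - 1L)))
    stop_format("'", path, "': frames must be consecutive from 0 (line ",
                which(d$frame != 0:(nrow(d) - 1L))[1L] + 1L, ")")
  if (all(d$label %in% c("0", "1"))) as.integer(d$label) else d$label
}

#' @rdname read_timeline
#' @export
write_timeline <- function(timeline, path) {
  d <- data.frame(frame = seq_along(timeline) - 1L,
                  label = as.character(timeline))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' Reads AOI parameters and pipeline options from a YAML file and merges
#' them over the documented defaults. Recognised keys: the [aoi_params()]
#' arguments, `max_distance` (Re-ID rejection threshold, default
#' unlimited) and `convention` (`net` or `framewise` normalized
#' difference).
#'
#' @param path YAML file path; `NULL` gives pure defaults.
#' @return List with `params` (an [aoi_params]), `max_distance`,
#'   `convention`.
#' @export
read_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop_config("config file not found: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  known <- c(names(formals(aoi_params)), "max_distance", "convention")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_config("unknown config keys: ", paste(unknown, collapse = ", "))
  pargs <- raw[intersect(names(raw), names(formals(aoi_params)))]
  max_distance <- if (is.null(raw$max_distance)) Inf else raw$max_distance
  convention <- if (is.null(raw$convention)) "net" else raw$convention
  if (!convention %in% c("net", "framewise"))
    stop_config("convention must be 'net' or 'framewise'")
  list(params = do.call(aoi_params, pargs),
       max_distance = max_distance, convention = convention)
}
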