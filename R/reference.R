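#' Published per-video agreement tables from a consultation study
#'
#' Summary agreement results between human annotators and the automated
#' pipeline on physician-patient consultation recordings: seven
#' one-minute videos scored single-class (`"single_minute"`) and
#' multiple-class with re-identification (`"multi_minute"`), plus two
#' full-length videos scored with rectangular and oval AOI shapes
#' (`"long_videos"`). Durations are in seconds, normalized differences in
#' percent of video duration (net convention, two decimals as
#' published).
#'
#' These tables serve as arithmetic reference points: the package's
#' [normalized_difference()] conventions and summary statistics can be
#' recomputed from the duration columns and compared against the
#' published `delta_s` and `normalized_delta_pct` columns.
#'
#' @param table which table to load.
#' @return data.frame.
#' @examples
#' tab <- reference_agreement("single_minute")
#' sum(tab$face_gaze_algo_s)  # 212.40 s of algorithm face-gaze
#' @export
reference_agreement <- function(table = c("single_minute", "multi_minute",
                                          "long_videos")) {
  table <- match.arg(table)
  file <- c(single_minute = "consultations_single_class.csv",
            multi_minute = "consultations_multi_class.csv",
            long_videos = "consultations_long_videos.csv")[[table]]
  path <- system.file("extdata", file, package = "faceAOI", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
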