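# Structured conditions so the CLI can map failures to exit codes
# (format error -> 2, config error -> 3).

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("faceaoi_input_error", "faceaoi_error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("faceaoi_format_error", "faceaoi_error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("faceaoi_config_error", "faceaoi_error")))
}
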