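# shared fixture builders; everything is generated in code

# random head keypoints with a given number of visible landmarks
random_keypoints <- function(n_visible, span = 100, origin = c(500, 400)) {
  idx <- sample.int(5L, n_visible)
  args <- stats::setNames(vector("list", 5L), HEAD_LANDMARKS)
  for (i in idx)
    args[[i]] <- c(origin[1] + stats::runif(1, -span, span),
                   origin[2] + stats::runif(1, -span, span), 0.9)
  do.call(head_keypoints, args)
}

# brute-force largest pairwise distance, independent of head_width()
brute_max_dist <- function(kp, conf_threshold = 0.1) {
  v <- visible_points(kp, conf_threshold)
  xy <- unclass(kp)[v, c("x", "y"), drop = FALSE]
  best <- 0
  for (i in seq_len(nrow(xy)))
    for (j in seq_len(nrow(xy)))
      best <- max(best, sqrt(sum((xy[i, ] - xy[j, ])^2)))
  best
}

# a small scene configuration that runs in milliseconds
quick_config <- function(seed, n_frames = 100L, ...) {
  scene_config(duration = n_frames / 25, seed = seed,
               frame_width = 960L, frame_height = 540L, head_scale = 60,
               ...)
}

# a synthetic binary timeline with a given number of 1-frames
ones_timeline <- function(n_ones, n_frames) {
  c(rep(1L, n_ones), rep(0L, n_frames - n_ones))
}
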