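# canonical landmark offsets relative to the head center, in units of
# head_scale; the ear-to-ear span is exactly one head_scale
.HEAD_LAYOUT <- matrix(c(
   0.00,  0.15,   # nose
  -0.20, -0.05,   # left_eye
   0.20, -0.05,   # right_eye
  -0.50,  0.00,   # left_ear
   0.50,  0.00),  # right_ear
  ncol = 2L, byrow = TRUE,
  dimnames = list(HEAD_LANDMARKS, c("x", "y")))

#' Configuration of a synthetic interaction scene
#'
#' Describes a simulated face-to-face interaction seen through a
#' head-worn scene camera: one or more heads moving smoothly around the
#' frame, switching between frontal and profile pose with landmark
#' dropout, identity-specific embedding clusters, and gaze that
#' alternates between dwelling on a face and looking elsewhere.
#'
#' Defaults mirror a one-minute consultation recording: a 1920 x 1080
#' scene camera at 25 Hz, two interactors with heads spanning about 120
#' pixels, and gaze on a face about half the time.
#'
#' @param n_identities number of people in the scene (>= 1).
#' @param duration scene length in seconds.
#' @param frame_width,frame_height scene-camera frame size in pixels.
#' @param head_scale nominal ear-to-ear span in pixels.
#' @param motion_step_sd per-frame random-walk step of each head center
#'   (pixels).
#' @param profile_prob per-frame probability a head shows a profile pose
#'   (2-4 visible landmarks) instead of frontal (all 5 visible).
#' @param dropout_prob probability that each eye of a profile pose is
#'   additionally invisible (the nose and near ear always remain, so a
#'   detected head never drops below 2 landmarks).
#' @param embedding_dim embedding dimensionality (128, the conventional
#'   appearance-descriptor size).
#' @param embedding_centroid_separation scale of the identity centroids
#'   in embedding space.
#' @param embedding_noise_sd per-component Gaussian noise around the
#'   identity centroid.
#' @param gaze_on_face_prob per-frame probability the gaze targets a
#'   (uniformly chosen) face.
#' @param gaze_jitter_sd Gaussian jitter added to the recorded gaze
#'   sample (pixels); the ground truth keeps the intended target.
#' @param seed integer master seed; all stochastic draws derive from it.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(n_identities = 2L, duration = 60,
                         frame_width = 1920L, frame_height = 1080L,
                         head_scale = 120, motion_step_sd = 3,
                         profile_prob = 0.2, dropout_prob = 0.1,
                         embedding_dim = 128L,
                         embedding_centroid_separation = 10,
                         embedding_noise_sd = 1,
                         gaze_on_face_prob = 0.5, gaze_jitter_sd = 0,
                         seed = 1L) {
  cfg <- list(n_identities = as.integer(n_identities), duration = duration,
              frame_width = as.integer(frame_width),
              frame_height = as.integer(frame_height),
              head_scale = head_scale, motion_step_sd = motion_step_sd,
              profile_prob = profile_prob, dropout_prob = dropout_prob,
              embedding_dim = as.integer(embedding_dim),
              embedding_centroid_separation = embedding_centroid_separation,
              embedding_noise_sd = embedding_noise_sd,
              gaze_on_face_prob = gaze_on_face_prob,
              gaze_jitter_sd = gaze_jitter_sd,
              seed = as.integer(seed))
  probs <- c(cfg$profile_prob, cfg$dropout_prob, cfg$gaze_on_face_prob)
  if (any(probs < 0 | probs > 1))
    stop_config("probabilities must lie in [0, 1]")
  if (cfg$n_identities < 1L) stop_config("n_identities must be >= 1")
  if (cfg$duration <= 0) stop_config("duration must be > 0")
  if (cfg$head_scale <= 0 || cfg$motion_step_sd < 0 ||
      cfg$embedding_noise_sd < 0 || cfg$gaze_jitter_sd < 0 ||
      cfg$embedding_centroid_separation <= 0)
    stop_config("scales must be positive")
  if (cfg$embedding_dim < cfg$n_identities)
    stop_config("embedding_dim must be >= n_identities")
  class(cfg) <- "scene_config"
  cfg
}

# substream seeding: each stochastic stage draws under its own seed
# derived from the master, so e.g. adding gaze jitter cannot shift the
# head trajectories
.with_substream <- function(seed, offset, expr) {
  set.seed((seed %% 1000000000L) + offset)
  expr
}

# identity labels; lexicographic order equals numeric order
.identity_labels <- function(n) sprintf("person_%02d", seq_len(n))

# per-identity horizontal band limits for the head-center walk, chosen so
# the largest possible AOI (plus a safety pad) stays inside the band and
# the frame; disjoint bands guarantee AOIs of different people never
# overlap, which keeps the nearest-center overlap rule out of play
.head_bounds <- function(cfg, params, pad = 4) {
  s <- cfg$head_scale
  wmax <- s * max(params$margin_frontal, params$margin_profile)
  hmax <- s * max(params$aspect_frontal * params$margin_frontal,
                  params$aspect_profile * params$margin_profile)
  # landmark centroid sits within 0.5 * head_scale of the head center;
  # the center offset can shift the box by up to one height
  slack_x <- wmax / 2 + 0.5 * s + pad
  slack_y <- hmax / 2 + 0.5 * s +
    max(abs(params$offset_frontal), abs(params$offset_profile)) * hmax + pad
  band_w <- cfg$frame_width / cfg$n_identities
  lo_x <- (seq_len(cfg$n_identities) - 1L) * band_w + slack_x
  hi_x <- seq_len(cfg$n_identities) * band_w - slack_x
  lo_y <- slack_y
  hi_y <- cfg$frame_height - slack_y
  if (any(hi_x <= lo_x) || hi_y <= lo_y)
    stop_config("heads cannot fit in the frame: shrink head_scale or the ",
                "AOI margins, or enlarge the frame")
  list(lo_x = lo_x, hi_x = hi_x, lo_y = lo_y, hi_y = hi_y)
}

# reflect a random walk into [lo, hi]
.reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Simulate a synthetic interaction scene
#'
#' Generates everything the annotation pipeline consumes — a keypoint
#' table, gaze samples, per-detection embeddings and a labelled gallery —
#' together with the ground-truth single-class and multiple-class
#' timelines. Ground truth is recorded from the generative choices (which
#' frames target which face), never by running the pipeline, so recovery
#' tests are genuine round trips.
#'
#' Gaze points intended to be on a face are placed strictly inside that
#' face's AOI (as built with `params`) with a 2-pixel buffer; off-face
#' points are placed strictly outside every AOI with the same buffer, so
#' boundary-inclusion conventions cannot flip the ground truth. Recorded
#' gaze samples additionally carry `gaze_jitter_sd` of Gaussian noise
#' while the ground truth keeps the intended label, which is how noisy
#' gaze degrades recovered agreement.
#'
#' @param config a [scene_config].
#' @param params the [aoi_params] the downstream pipeline will use.
#' @return List with `keypoints`, `gaze`, `embeddings` (data.frames in
#'   the package file dialects), `gallery` (a [reid_gallery] holding one
#'   centroid entry per identity), `aois` (the ground-truth AOI table),
#'   `truth_single`, `truth_multi`, `identities`, `n_frames`, plus the
#'   `config` and `params` used.
#' @export
simulate_scene <- function(config, params = aoi_params()) {
  stopifnot(inherits(config, "scene_config"), inherits(params, "aoi_params"))
  n_frames <- frames_for_duration(config$duration)
  n_id <- config$n_identities
  ids <- .identity_labels(n_id)
  b <- .head_bounds(config, params)

  # head-center trajectories: reflected Gaussian random walks per identity
  centers <- .with_substream(config$seed, 1L, {
    lapply(seq_len(n_id), function(i) {
      x0 <- (b$lo_x[i] + b$hi_x[i]) / 2
      y0 <- (b$lo_y + b$hi_y) / 2
      dx <- stats::rnorm(n_frames, 0, config$motion_step_sd)
      dy <- stats::rnorm(n_frames, 0, config$motion_step_sd)
      cbind(x = .reflect(x0 + cumsum(dx), b$lo_x[i], b$hi_x[i]),
            y = .reflect(y0 + cumsum(dy), b$lo_y, b$hi_y))
    })
  })

  # per-frame pose and landmark visibility
  vis <- .with_substream(config$seed, 2L, {
    lapply(seq_len(n_id), function(i) {
      profile <- stats::runif(n_frames) < config$profile_prob
      side_left <- stats::runif(n_frames) < 0.5
      eye_near <- stats::runif(n_frames) >= config$dropout_prob
      eye_far <- stats::runif(n_frames) >= config$dropout_prob
      v <- matrix(TRUE, n_frames, 5L, dimnames = list(NULL, HEAD_LANDMARKS))
      # profile: far ear always hidden, eyes subject to dropout
      v[profile & side_left, "right_ear"] <- FALSE
      v[profile & !side_left, "left_ear"] <- FALSE
      v[profile, "left_eye"] <- ifelse(side_left[profile], eye_near[profile],
                                       eye_far[profile])
      v[profile, "right_eye"] <- ifelse(side_left[profile], eye_far[profile],
                                        eye_near[profile])
      v
    })
  })

  # wide keypoint table, one row per person per frame
  kp_blocks <- lapply(seq_len(n_id), function(i) {
    blk <- data.frame(frame = 0:(n_frames - 1L), person = i - 1L)
    for (k in seq_len(5L)) {
      p <- unname(.LANDMARK_PREFIX[k])
      x <- centers[[i]][, "x"] + .HEAD_LAYOUT[k, "x"] * config$head_scale
      y <- centers[[i]][, "y"] + .HEAD_LAYOUT[k, "y"] * config$head_scale
      v <- vis[[i]][, k]
      blk[[paste0(p, "_x")]] <- ifelse(v, x, NA_real_)
      blk[[paste0(p, "_y")]] <- ifelse(v, y, NA_real_)
      blk[[paste0(p, "_c")]] <- ifelse(v, 0.9, 0)
    }
    blk
  })
  keypoints <- do.call(rbind, kp_blocks)
  keypoints <- keypoints[order(keypoints$frame, keypoints$person), ]
  rownames(keypoints) <- NULL

  # ground-truth AOI geometry for gaze placement (same arithmetic the
  # pipeline applies; the truth labels below come from the draws, not
  # from hit testing)
  aois <- build_aois(keypoints, params)
  aoi_key <- paste(aois$frame, aois$person)
  aois$identity <- ids[aois$person + 1L]

  # gaze targets and points
  buf <- 2
  gaze_draw <- .with_substream(config$seed, 3L, {
    on_face <- stats::runif(n_frames) < config$gaze_on_face_prob
    target <- sample.int(n_id, n_frames, replace = TRUE)
    u1 <- stats::runif(n_frames); u2 <- stats::runif(n_frames)
    list(on_face = on_face, target = target, u1 = u1, u2 = u2)
  })
  px <- numeric(n_frames); py <- numeric(n_frames)
  aoi_rows <- match(paste(0:(n_frames - 1L), gaze_draw$target - 1L), aoi_key)
  for (f in seq_len(n_frames)) {
    if (gaze_draw$on_face[f]) {
      a <- aois[aoi_rows[f], ]
      hw <- a$width / 2 - buf
      hh <- a$height / 2 - buf
      if (hw <= 0 || hh <= 0)
        stop_config("AOI too small for the interior buffer; increase head_scale")
      if (params$shape == "oval") {
        r <- sqrt(gaze_draw$u1[f]); th <- 2 * pi * gaze_draw$u2[f]
        px[f] <- a$center_x + r * hw * cos(th)
        py[f] <- a$center_y + r * hh * sin(th)
      } else {
        px[f] <- a$center_x + (2 * gaze_draw$u1[f] - 1) * hw
        py[f] <- a$center_y + (2 * gaze_draw$u2[f] - 1) * hh
      }
    }
  }
  # off-face points: uniform over the frame, rejected while within `buf`
  # of any AOI of that frame
  off_idx <- which(!gaze_draw$on_face)
  if (length(off_idx) > 0L) {
    frame_aois <- split(seq_len(nrow(aois)), aois$frame)
    .with_substream(config$seed, 4L, {
      for (f in off_idx) {
        rows <- frame_aois[[as.character(f - 1L)]]
        a <- aois[rows, , drop = FALSE]
        repeat {
          x <- stats::runif(1L, 0, config$frame_width)
          y <- stats::runif(1L, 0, config$frame_height)
          dx <- (x - a$center_x) / (a$width / 2 + buf)
          dy <- (y - a$center_y) / (a$height / 2 + buf)
          outside <- if (params$shape == "oval") dx^2 + dy^2 > 1
                     else abs(dx) > 1 | abs(dy) > 1
          if (all(outside)) { px[f] <- x; py[f] <- y; break }
        }
      }
    })
  }
  jit <- .with_substream(config$seed, 5L, {
    cbind(stats::rnorm(n_frames, 0, config$gaze_jitter_sd),
          stats::rnorm(n_frames, 0, config$gaze_jitter_sd))
  })
  gaze <- data.frame(timestamp_ms = 0:(n_frames - 1L) * 40 + 20,
                     x_px = px + jit[, 1L], y_px = py + jit[, 2L],
                     valid = TRUE)

  # embeddings: identity-specific Gaussian clusters around orthogonal
  # centroids; the gallery holds the noiseless centroid of each identity
  centroids <- matrix(0, n_id, config$embedding_dim)
  centroids[cbind(seq_len(n_id), seq_len(n_id))] <-
    config$embedding_centroid_separation
  emb_noise <- .with_substream(config$seed, 6L, {
    matrix(stats::rnorm(n_frames * n_id * config$embedding_dim,
                        0, config$embedding_noise_sd),
           nrow = n_frames * n_id)
  })
  emb_person <- rep(0:(n_id - 1L), times = n_frames)
  emb_frame <- rep(0:(n_frames - 1L), each = n_id)
  E <- centroids[emb_person + 1L, , drop = FALSE] + emb_noise
  embeddings <- data.frame(frame = emb_frame, person = emb_person)
  colnames(E) <- paste0("e", seq_len(config$embedding_dim) - 1L)
  embeddings <- cbind(embeddings, as.data.frame(E))

  truth_single <- as.integer(gaze_draw$on_face)
  truth_multi <- ifelse(gaze_draw$on_face, ids[gaze_draw$target], "0")

  list(keypoints = keypoints, gaze = gaze, embeddings = embeddings,
       gallery = reid_gallery(centroids, ids),
       aois = aois, truth_single = truth_single, truth_multi = truth_multi,
       identities = ids, n_frames = n_frames,
       config = config, params = params)
}

#' Run the full pipeline on a simulated scene and score recovery
#'
#' Builds AOIs from the simulated keypoints, annotates the single- and
#' multiple-class timelines from the simulated gaze, re-identifies every
#' detection against the gallery, and scores everything against the
#' ground truth with the agreement module. With zero embedding noise and
#' zero gaze jitter, recovery is exact: kappa 1 and Re-ID accuracy 100%.
#'
#' @inheritParams simulate_scene
#' @return List with `kappa` (single-class, vs ground truth),
#'   `kappa_multi`, `accuracy_pct`, `reid_accuracy_pct` (per-detection
#'   identity assignment accuracy), and `n_frames`.
#' @export
pipeline_recovery_check <- function(config, params = aoi_params()) {
  sc <- simulate_scene(config, params)
  aois <- build_aois(sc$keypoints, params)
  tl_single <- annotate_single_class(sc$gaze, aois, sc$n_frames)
  assigned <- assign_identities(sc$embeddings, sc$gallery)
  aois$identity <- assigned$identity[match(paste(aois$frame, aois$person),
                                           paste(assigned$frame, assigned$person))]
  tl_multi <- annotate_multi_class(sc$gaze, aois, sc$n_frames)
  true_det <- sc$identities[sc$embeddings$person + 1L]
  cm <- confusion_matrix(true_det, assigned$identity)
  kappa <- suppressWarnings(cohens_kappa(sc$truth_single, tl_single))
  kappa_multi <- suppressWarnings(cohens_kappa(sc$truth_multi, tl_multi))
  list(kappa = kappa, kappa_multi = kappa_multi,
       accuracy_pct = frame_accuracy(sc$truth_single, tl_single),
       reid_accuracy_pct = cm$accuracy_pct,
       n_frames = sc$n_frames)
}
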