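test_that("durations convert to 25 Hz frame counts by rounding", {
  expect_identical(frames_for_duration(1), 25L)
  expect_identical(frames_for_duration(421.04), 10526L)
  expect_identical(frames_for_duration(1102.76), 27569L)
  expect_identical(frames_for_duration(0), 0L)
  expect_error(frames_for_duration(-1), class = "faceaoi_input_error")
})

test_that("each frame takes the valid sample nearest its midpoint", {
  s <- data.frame(timestamp_ms = c(0, 10, 20, 30), x_px = 1:4, y_px = 11:14,
                  valid = TRUE)
  expect_equal(gaze_for_frame(s, 0), c(x = 3, y = 13))

  # empty window -> missing
  expect_null(gaze_for_frame(s, 1))

  # exact tie to the midpoint breaks toward the earlier sample
  tie <- data.frame(timestamp_ms = c(15, 25), x_px = c(100, 200),
                    y_px = c(0, 0), valid = TRUE)
  expect_equal(gaze_for_frame(tie, 0)[["x"]], 100)

  # exhaustive check of the tie rule over every in-window offset pair
  for (t1 in seq(0, 39, by = 1)) for (t2 in seq(t1 + 1, 40, by = 13)) {
    if (t2 >= 40) next
    two <- data.frame(timestamp_ms = c(t1, t2), x_px = c(1, 2), y_px = c(0, 0),
                      valid = TRUE)
    want <- if (abs(t1 - 20) <= abs(t2 - 20)) 1 else 2
    expect_equal(gaze_for_frame(two, 0)[["x"]], want)
  }

  # invalid samples never win
  inv <- data.frame(timestamp_ms = c(19, 35), x_px = c(1, 2), y_px = c(0, 0),
                    valid = c(FALSE, TRUE))
  expect_equal(gaze_for_frame(inv, 0)[["x"]], 2)
})

test_that("hit testing is boundary inclusive and shape aware", {
  rect <- list(shape = "rectangle", center_x = 15, center_y = 0,
               width = 30, height = 30)
  expect_true(hit_test(c(15, 0), rect))
  expect_true(hit_test(c(30, 15), rect))   # corner, inclusive
  expect_false(hit_test(c(30.01, 15), rect))

  oval <- rect; oval$shape <- "oval"
  expect_true(hit_test(c(15, 0), oval))
  expect_false(hit_test(c(30, 15), oval))  # corner lies outside the ellipse
  expect_true(hit_test(c(30, 0), oval))    # semi-axis endpoint, inclusive

  # the oval is inscribed in the rectangle: oval hit implies rectangle hit
  set.seed(77)
  for (i in 1:200) {
    p <- c(runif(1, -20, 50), runif(1, -35, 35))
    if (hit_test(p, oval)) expect_true(hit_test(p, rect))
  }
})

test_that("single-class annotation labels any-face hits and nothing else", {
  aois <- data.frame(frame = c(0L, 2L), person = 0L, shape = "rectangle",
                     center_x = 100, center_y = 100, width = 50, height = 50,
                     identity = NA_character_, stringsAsFactors = FALSE)
  gaze <- data.frame(timestamp_ms = c(20, 60, 100),
                     x_px = c(100, 100, 500), y_px = c(100, 100, 500),
                     valid = TRUE)
  tl <- annotate_single_class(gaze, aois, 4L)
  # frame 0: hit; frame 1: gaze but no AOI; frame 2: gaze off the AOI;
  # frame 3: no gaze at all
  expect_identical(as.integer(tl), c(1L, 0L, 0L, 0L))
  expect_identical(attr(tl, "n_missing_gaze"), 1L)

  # invalid gaze counts as missing, hence 0
  gaze$valid <- c(FALSE, TRUE, TRUE)
  tl2 <- annotate_single_class(gaze, aois, 4L)
  expect_identical(as.integer(tl2), c(0L, 0L, 0L, 0L))
})

test_that("multi-class annotation resolves overlap by nearest AOI center", {
  aois <- data.frame(frame = 0L, person = 0:1, shape = "rectangle",
                     center_x = c(100, 140), center_y = 100,
                     width = 80, height = 80,
                     identity = c("patient", "caregiver"),
                     stringsAsFactors = FALSE)
  hit_both_near_patient <- data.frame(timestamp_ms = 20, x_px = 115,
                                      y_px = 100, valid = TRUE)
  expect_identical(annotate_multi_class(hit_both_near_patient, aois, 1L)[1],
                   "patient")
  hit_both_near_caregiver <- data.frame(timestamp_ms = 20, x_px = 125,
                                        y_px = 100, valid = TRUE)
  expect_identical(annotate_multi_class(hit_both_near_caregiver, aois, 1L)[1],
                   "caregiver")
  off_all <- data.frame(timestamp_ms = 20, x_px = 700, y_px = 700, valid = TRUE)
  expect_identical(annotate_multi_class(off_all, aois, 1L)[1], "0")

  untagged <- aois; untagged$identity <- NA_character_
  expect_error(annotate_multi_class(off_all, untagged, 1L),
               class = "faceaoi_input_error")
})

test_that("face-gaze duration counts non-zero frames at 40 ms each", {
  expect_equal(face_gaze_duration(ones_timeline(666, 1500)), 26.64)
  expect_equal(face_gaze_duration(rep(0, 100)), 0)
  multi <- c(rep("patient", 765), rep("researcher", 10), rep("0", 725))
  expect_equal(face_gaze_duration(multi, identity = "patient"), 30.60)
  expect_equal(face_gaze_duration(multi), 31.0)
})

test_that("identity durations conserve the total timeline duration", {
  set.seed(88)
  for (i in 1:5) {
    sc <- simulate_scene(quick_config(800 + i, n_frames = 80L,
                                      n_identities = 2L))
    tl <- sc$truth_multi
    per_id <- vapply(sc$identities, function(id) face_gaze_duration(tl, id),
                     numeric(1))
    off <- sum(tl == "0") * 0.04
    expect_equal(sum(per_id) + off, length(tl) * 0.04)
  }
})

test_that("single-class equals multi-class collapsed to any-face", {
  for (i in 1:10) {
    sc <- simulate_scene(quick_config(900 + i, n_frames = 60L,
                                      n_identities = sample(1:3, 1)))
    aois <- build_aois(sc$keypoints, sc$params)
    aois$identity <- sc$identities[aois$person + 1L]
    single <- annotate_single_class(sc$gaze, aois, sc$n_frames)
    multi <- annotate_multi_class(sc$gaze, aois, sc$n_frames)
    expect_identical(as.integer(single), as.integer(multi != "0"))
  }
})
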