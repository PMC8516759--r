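test_that("orientation follows the visible-landmark count", {
  full <- head_keypoints(nose = c(0, 0), left_eye = c(-5, -5),
                         right_eye = c(5, -5), left_ear = c(-15, 0),
                         right_ear = c(15, 0))
  expect_identical(classify_orientation(full), "frontal")

  two <- head_keypoints(nose = c(0, 0), left_eye = c(-5, -5))
  expect_identical(classify_orientation(two), "profile")

  set.seed(11)
  for (k in 2:4)
    expect_identical(classify_orientation(random_keypoints(k)), "profile")

  one <- head_keypoints(nose = c(0, 0))
  expect_identical(classify_orientation(one), "undetected")
  none <- head_keypoints()
  expect_identical(classify_orientation(none), "undetected")

  # a low-confidence landmark does not count as visible
  faded <- head_keypoints(nose = c(0, 0, 0.9), left_eye = c(-5, -5, 0.05))
  expect_identical(classify_orientation(faded), "undetected")
})

test_that("head width is the largest pairwise distance over visible points", {
  kp <- head_keypoints(nose = c(0, 0), left_ear = c(3, 4))
  expect_equal(head_width(kp), 5)

  row <- head_keypoints(nose = c(0, 0), left_eye = c(10, 0),
                        right_eye = c(20, 0), left_ear = c(30, 0),
                        right_ear = c(40, 0))
  expect_equal(head_width(row), 40)

  set.seed(21)
  for (i in 1:25) {
    kp <- random_keypoints(sample(2:5, 1))
    expect_equal(head_width(kp), brute_max_dist(kp))
  }

  expect_error(head_width(head_keypoints(nose = c(0, 0))),
               class = "faceaoi_input_error")
})

test_that("build_aoi applies the width/aspect/margin/offset formulas", {
  prof <- head_keypoints(nose = c(0, 0), left_ear = c(30, 0))
  a <- build_aoi(prof, aoi_params(aspect_profile = 1, margin_profile = 1))
  expect_equal(a$center_x, 15)
  expect_equal(a$center_y, 0)
  expect_equal(a$width, 30)
  expect_equal(a$height, 30)
  expect_identical(a$shape, "rectangle")

  # frontal face with head width 30: width 30 x 1.1, height 30 x 1.2 x 1.1
  front <- head_keypoints(nose = c(0, 5), left_eye = c(-5, -5),
                          right_eye = c(5, -5), left_ear = c(-15, 0),
                          right_ear = c(15, 0))
  b <- build_aoi(front, aoi_params(aspect_frontal = 1.2, margin_frontal = 1.1))
  expect_equal(b$width, 33)
  expect_equal(b$height, 39.6)

  # vertical center offset moves the box by a fraction of its height
  c_ <- build_aoi(prof, aoi_params(aspect_profile = 1, margin_profile = 1,
                                   offset_profile = 0.25))
  expect_equal(c_$center_y, 0.25 * 30)

  expect_null(build_aoi(head_keypoints(nose = c(0, 0)), aoi_params()))
  expect_null(build_aoi(head_keypoints(), aoi_params()))
})

test_that("margin scales both dimensions, aspect only the height", {
  set.seed(31)
  for (i in 1:10) {
    kp <- random_keypoints(sample(2:5, 1))
    base <- build_aoi(kp, aoi_params(aspect_frontal = 1.3, aspect_profile = 1.1,
                                     margin_frontal = 1.0, margin_profile = 1.0))
    bigger <- build_aoi(kp, aoi_params(aspect_frontal = 1.3, aspect_profile = 1.1,
                                       margin_frontal = 1.5, margin_profile = 1.5))
    expect_gt(bigger$width, base$width)
    expect_gt(bigger$height, base$height)
    taller <- build_aoi(kp, aoi_params(aspect_frontal = 1.6, aspect_profile = 1.4,
                                       margin_frontal = 1.0, margin_profile = 1.0))
    expect_equal(taller$width, base$width)
    expect_gt(taller$height, base$height)
  }
})

test_that("the AOI box contains every visible keypoint", {
  set.seed(41)
  for (i in 1:30) {
    kp <- random_keypoints(sample(2:5, 1))
    a <- build_aoi(kp, aoi_params(margin_frontal = 1, margin_profile = 1,
                                  aspect_frontal = 1, aspect_profile = 1))
    v <- visible_points(kp)
    xy <- unclass(kp)[v, c("x", "y"), drop = FALSE]
    for (r in seq_len(nrow(xy)))
      expect_true(hit_test(xy[r, ], a))
  }
})

test_that("AOIs are translation equivariant", {
  set.seed(51)
  kp <- random_keypoints(4)
  shift <- c(123.5, -67.25)
  m <- unclass(kp)
  shifted <- do.call(head_keypoints, stats::setNames(lapply(1:5, function(i) {
    if (m[i, "conf"] == 0) NULL else c(m[i, "x"] + shift[1], m[i, "y"] + shift[2], m[i, "conf"])
  }), HEAD_LANDMARKS))
  a <- build_aoi(kp, aoi_params())
  b <- build_aoi(shifted, aoi_params())
  expect_equal(b$center_x, a$center_x + shift[1])
  expect_equal(b$center_y, a$center_y + shift[2])
  expect_equal(b$width, a$width)
  expect_equal(b$height, a$height)
})

test_that("oval and rectangle share the bounding box", {
  set.seed(61)
  kp <- random_keypoints(5)
  rect <- build_aoi(kp, aoi_params(shape = "rectangle"))
  oval <- build_aoi(kp, aoi_params(shape = "oval"))
  expect_equal(oval$center_x, rect$center_x)
  expect_equal(oval$center_y, rect$center_y)
  expect_equal(oval$width, rect$width)
  expect_equal(oval$height, rect$height)
})

test_that("vectorized AOI construction matches the scalar path", {
  sc <- simulate_scene(quick_config(71, n_frames = 40L))
  params <- aoi_params(shape = "oval", offset_profile = -0.1)
  tab <- build_aois(sc$keypoints, params)
  for (i in sample(nrow(sc$keypoints), 15)) {
    a <- build_aoi(faceAOI:::keypoints_from_row(sc$keypoints[i, , drop = FALSE]), params)
    j <- which(tab$frame == sc$keypoints$frame[i] &
                 tab$person == sc$keypoints$person[i])
    expect_equal(tab$center_x[j], a$center_x)
    expect_equal(tab$center_y[j], a$center_y)
    expect_equal(tab$width[j], a$width)
    expect_equal(tab$height[j], a$height)
    expect_identical(tab$orientation[j], a$orientation)
  }
})

test_that("invalid AOI parameters are rejected as configuration errors", {
  expect_error(aoi_params(aspect_frontal = 0), class = "faceaoi_config_error")
  expect_error(aoi_params(margin_profile = -1), class = "faceaoi_config_error")
  expect_error(aoi_params(offset_frontal = 1.5), class = "faceaoi_config_error")
})
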