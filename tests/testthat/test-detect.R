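test_that("sum projection handles trivial and derived cases", {
  z <- array(0, c(4, 5, 3))
  expect_equal(sum_projection(z), matrix(0, 4, 5))
  one <- array(runif(20), c(4, 5, 1))
  expect_equal(sum_projection(one), one[, , 1])
  s <- array(rep(c(1, 2, 4), each = 20), c(4, 5, 3))
  expect_equal(sum_projection(s), matrix(7, 4, 5))
  expect_error(sum_projection(array(0, c(2, 2, 0))), "plane")
})

test_that("sum projection is linear in intensity", {
  st <- array(runif(4 * 5 * 3) * 10, c(4, 5, 3))
  expect_equal(sum_projection(3.7 * st), 3.7 * sum_projection(st))
})

test_that("diameter bounds keep the 1-um bead and reject 0.3 and 2.5 um objects", {
  img <- matrix(0, 120, 120)
  img <- add_sharp_disk(img, 20, 20, 0.3, 50)
  img <- add_sharp_disk(img, 60, 60, 1.0, 50)
  img <- add_sharp_disk(img, 100, 100, 2.5, 50)
  det <- detect_spots(img, detection_params(), pixel_size_um = 0.25)
  expect_identical(nrow(det), 1L)
  expect_equal(det$x_px, 60, tolerance = 0.02)
  expect_equal(det$y_px, 60, tolerance = 0.02)
  expect_gte(det$eq_diameter_um, 0.5)
  expect_lte(det$eq_diameter_um, 1.5)
})

test_that("a blank image yields zero detections", {
  det <- detect_spots(matrix(0, 50, 50), detection_params(), 0.25)
  expect_identical(nrow(det), 0L)
})

test_that("planted noise-free beads are all recovered with sub-pixel accuracy", {
  sc <- clean_scene(20, seed = 31)
  proj <- sum_projection(sc$volumes[["green_490_530"]])
  det <- detect_spots(proj, detection_params(), sc$config$pixel_size_um)
  expect_identical(nrow(det), 20L)
  px <- sc$config$pixel_size_um
  for (i in seq_len(nrow(det))) {
    d <- sqrt((sc$truth$x_um - det$x_um[i])^2 + (sc$truth$y_um - det$y_um[i])^2)
    expect_lt(min(d), px)  # within 1 pixel of a planted centre
  }
  expect_true(all(det$eq_diameter_um >= 0.5 & det$eq_diameter_um <= 1.5))
  expect_false(any(det$clump))
})

test_that("raising the threshold never increases the detection count", {
  sc <- generate_scene(scene_config(width_um = 32, height_um = 32, depth_um = 30),
                       seed = 8)
  sc <- plant_beads(sc, 15, seed = 9)
  proj <- sum_projection(sc$volumes[["green_490_530"]])
  thresholds <- c(5, 10, 20, 40, 80, 200)
  counts <- vapply(thresholds, function(thr) {
    nrow(detect_spots(proj, detection_params(threshold = thr), 0.25))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("no returned non-clump detection violates the diameter bounds", {
  sc <- generate_scene(scene_config(width_um = 48, height_um = 48, depth_um = 30),
                       seed = 14)
  sc <- plant_beads(sc, 30, seed = 15, clump_fraction = 0.15)
  proj <- sum_projection(sc$volumes[["green_490_530"]])
  det <- detect_spots(proj, detection_params(threshold = 15), 0.25)
  ok <- det$eq_diameter_um[!det$clump]
  expect_true(all(ok >= 0.5 & ok <= 1.5))
})

test_that("threshold calibration minimizes summed count error with low-tie preference", {
  set.seed(77)
  mk <- function() {
    img <- matrix(0, 120, 120)
    pos <- expand.grid(x = seq(12, 108, by = 24), y = seq(12, 108, by = 24))
    for (i in seq_len(20)) {
      img <- add_sharp_disk(img, pos$x[i], pos$y[i], 1.0, 8)
    }
    # faint speckle patches detectable only at very low thresholds
    for (k in 1:5) {
      i0 <- sample(5:110, 1); j0 <- sample(5:110, 1)
      img[i0:(i0 + 2), j0:(j0 + 2)] <- img[i0:(i0 + 2), j0:(j0 + 2)] + 2
    }
    img
  }
  projs <- list(mk(), mk())  # two representative data sets
  thr <- calibrate_threshold(projs, c(20, 20), c(1, 5, 10), detection_params(), 0.25)
  expect_identical(thr, 5)
  # all thresholds perfect -> smallest returned
  clean <- matrix(0, 60, 60)
  clean <- add_sharp_disk(clean, 30, 30, 1.0, 100)
  expect_identical(
    calibrate_threshold(list(clean), 1, c(20, 40, 60), detection_params(), 0.25),
    20)
  expect_error(calibrate_threshold(list(), integer(0), c(1), detection_params(), 0.25),
               "non-empty")
})

test_that("best-focus plane is the axial argmax of footprint signal", {
  sc <- clean_scene(1, seed = 41, width_um = 20, height_um = 20,
                    depth_um = 100)
  st <- sc$volumes[["green_490_530"]]
  proj <- sum_projection(st)
  det <- detect_spots(proj, detection_params(), 0.25)
  expect_identical(nrow(det), 1L)
  z <- best_focus_plane(st, det[1, ], focus_threshold = 20, pixel_size_um = 0.25)
  # oracle: brute-force argmax of the bead-pixel axial profile
  j <- floor(det$x_px[1]) + 1; i <- floor(det$y_px[1]) + 1
  expect_identical(z, which.max(st[i, j, ]))
  # and it matches the plane nearest the planted z
  expect_equal((z - 0.5) * 10, sc$truth$z_um[1], tolerance = 5)

  # single-plane stack: plane 1
  one <- st[, , which.max(st[i, j, ]), drop = FALSE]
  expect_identical(best_focus_plane(one, det[1, ], 20, 0.25), 1L)

  # focus threshold above the bead's maximum: no plane qualifies
  expect_identical(best_focus_plane(st, det[1, ], 1e6, 0.25), NA_integer_)
})

test_that("best-focus errors when the footprint lies outside the stack", {
  st <- array(0, c(20, 20, 3))
  fake <- data.frame(x_px = 100, y_px = 5, eq_diameter_um = 1)
  expect_error(best_focus_plane(st, fake, 0, 0.25), "outside")
})
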