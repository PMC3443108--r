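test_that("stitching a single tile returns the tile projection", {
  sc <- clean_scene(5, seed = 1)
  ts <- tile_scene(sc, 1, 1, 0.1)
  comp <- stitch(ts, channel = "green_490_530")
  expect_equal(comp$images[["green_490_530"]],
               sum_projection(sc$volumes[["green_490_530"]]))
})

test_that("all-zero tiles stitch to an all-zero composite", {
  sc <- generate_scene(clean_config(), seed = 1)
  comp <- stitch(tile_scene(sc, 2, 2, 0.1))
  expect_true(all(vapply(comp$images, function(m) all(m == 0), logical(1))))
})

test_that("global mapping adds the tile offset and round-trips", {
  layout <- layout_tiles(1, 2, c(300, 400), 0.1)
  det <- data.frame(x_px = 10, y_px = 20, x_um = 2.5, y_um = 5,
                    peak = 50, eq_diameter_um = 1, area_px = 12,
                    clump = FALSE, z_best = NA_integer_,
                    tile_row = 1L, tile_col = 2L)
  g <- to_global(det, layout, 0.25)
  expect_equal(g$x_px, 370)
  expect_equal(g$y_px, 20)
  expect_equal(g$x_um, 370 * 0.25)
  # tile (1,1): unchanged
  det$tile_col <- 1L
  g0 <- to_global(det, layout, 0.25)
  expect_equal(g0$x_px, 10)
  # inverse: subtracting the offset recovers the in-tile position
  expect_equal(g$x_px - layout$offsets$x_px[layout$offsets$col == 2], g$x_px_tile)
  det$tile_col <- 5L
  expect_error(to_global(det, layout, 0.25), "outside the grid")
})

test_that("one bead in the overlap strip is detected twice but counted once", {
  # seed 19 places the single bead at x ~ 29.1 um; with a 0.5 overlap on a
  # 60-um-wide scene the two tiles cover 0-40 and 20-60 um, so the bead lies
  # in the shared strip and is detected by both tiles
  sc <- generate_scene(clean_config(width_um = 60, height_um = 30), seed = 1)
  sc <- plant_beads(sc, 1, seed = 19)
  expect_true(sc$truth$x_um > 24 && sc$truth$x_um < 36)
  ts <- tile_scene(sc, 1, 2, 0.5)
  raw <- detect_tileset(ts)
  expect_identical(nrow(raw), 2L)
  expect_identical(sort(raw$tile_col), c(1L, 2L))
  dd <- deduplicate(raw)
  expect_identical(nrow(dd), 1L)
  expect_identical(count_sample(ts), 1L)
})

test_that("detections outside overlaps pass through deduplication", {
  det <- data.frame(x_um = c(5, 50), y_um = c(5, 50), peak = c(10, 20),
                    tile_row = c(1L, 1L), tile_col = c(1L, 2L))
  expect_identical(nrow(deduplicate(det, 1.5)), 2L)
})

test_that("same-tile neighbours are never merged", {
  det <- data.frame(x_um = c(5, 5.5), y_um = c(5, 5), peak = c(10, 20),
                    tile_row = c(1L, 1L), tile_col = c(1L, 1L))
  expect_identical(nrow(deduplicate(det, 1.5)), 2L)
})

test_that("deduplication is idempotent and order-independent", {
  set.seed(123)
  n <- 30
  det <- data.frame(x_um = runif(n, 0, 40), y_um = runif(n, 0, 40),
                    peak = runif(n, 10, 100),
                    tile_row = sample(1:2, n, TRUE), tile_col = sample(1:2, n, TRUE))
  d1 <- deduplicate(det, 2)
  d2 <- deduplicate(d1, 2)
  expect_identical(nrow(d1), nrow(d2))
  expect_equal(sort(d1$x_um), sort(d2$x_um))
  perm <- det[sample.int(n), ]
  dp <- deduplicate(perm, 2)
  expect_identical(nrow(dp), nrow(d1))
  expect_equal(sort(dp$x_um), sort(d1$x_um))
  expect_lte(nrow(d1), nrow(det))
})

test_that("end-to-end count equals planted truth on 2x2 mosaics with overlap beads", {
  for (seed in c(101, 202)) {
    sc <- clean_scene(50, seed = seed, width_um = 60, height_um = 60)
    ts <- tile_scene(sc, 2, 2, 0.1)
    raw <- detect_tileset(ts)
    expect_gte(nrow(raw), 50)           # overlap strips produce duplicates
    expect_identical(count_sample(ts), 50L)
  }
})

test_that("the count is invariant under tile processing order", {
  sc <- clean_scene(30, seed = 55, width_um = 60, height_um = 60)
  ts <- tile_scene(sc, 2, 2, 0.1)
  base <- count_sample(ts)
  ts_rev <- ts
  ts_rev$tiles <- rev(ts_rev$tiles)
  expect_identical(count_sample(ts_rev), base)
  sc0 <- generate_scene(clean_config(), seed = 1)
  expect_identical(count_sample(tile_scene(sc0, 2, 2, 0.1)), 0L)
})
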