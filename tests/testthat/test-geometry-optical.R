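test_that("cylinder volume matches pi r^2 h and scales linearly", {
  g <- tube_geometry()
  expect_equal(cylinder_volume(1, g), pi * 64)
  expect_equal(cylinder_volume(0, g), 0)
  expect_equal(cylinder_volume(2.4, g), 2 * cylinder_volume(1.2, g))
  expect_error(cylinder_volume(-1, g), "non-negative")
})

test_that("cylinder volume agrees with a voxel-counting oracle", {
  # brute force: count ~1e6 voxels of a discretized cylinder r=8, h=1
  g <- tube_geometry(radius_mm = 8)
  dx <- 0.016
  xs <- seq(-8 + dx / 2, 8 - dx / 2, by = dx)
  inside <- outer(xs^2, xs^2, "+") <= 64
  v_voxel <- sum(inside) * dx * dx * 1
  expect_equal(v_voxel, cylinder_volume(1, g), tolerance = 0.01)
})

test_that("pixel-to-mm conversion uses the calibration", {
  cal <- pixel_calibration(50)
  expect_equal(heights_from_pixels(50, cal), 1.0)
  expect_equal(heights_from_pixels(1, cal), 0.02)  # single-pixel accuracy
  expect_equal(heights_from_pixels(0, cal), 0)
  expect_error(heights_from_pixels(-2, cal), "non-negative")
})

test_that("rendered layer heights are recovered within one pixel", {
  img <- render_tube_image(layer_heights(3.00, 5.00), seed = 101)
  m <- measure_layer_heights(img)
  expect_lte(abs(m$penetration_depth_mm - 3.00), 0.02)
  expect_lte(abs(m$increase_height_mm - 5.00), 0.02)
  expect_null(m$flag)
})

test_that("recovery is invariant under pixel noise", {
  set.seed(55)
  for (i in 1:20) {
    h_p <- stats::runif(1, 0.2, 4)
    h_i <- stats::runif(1, 0.2, 4)
    img <- render_tube_image(layer_heights(h_p, h_i), noise_sd = 5,
                             seed = 1000 + i)
    m <- measure_layer_heights(img)
    expect_lte(abs(m$penetration_depth_mm - h_p), 0.02)
    expect_lte(abs(m$increase_height_mm - h_i), 0.02)
  }
})

test_that("an image with no reacted band yields zero heights and a flag", {
  img <- render_tube_image(layer_heights(0, 0), seed = 9)
  m <- measure_layer_heights(img)
  expect_equal(m$penetration_depth_mm, 0)
  expect_equal(m$increase_height_mm, 0)
  expect_equal(m$flag, "no_reacted_band")
})

test_that("non-monotone zone ordering is rejected", {
  # dark band floating above the bright band: solution / sebum / reacted
  img <- matrix(128, nrow = 40, ncol = 8)
  img[15:20, ] <- 30
  img[21:30, ] <- 220
  img[31:40, ] <- 30
  expect_error(measure_layer_heights(tube_image(img, baseline_row = 21)),
               "non-monotone")
})

test_that("heights map to volumes through the tube cross-section", {
  v <- heights_to_volumes(layer_heights(1.03, 0))
  expect_equal(unname(v["v_penetrated_mm3"]), pi * 64 * 1.03)
  expect_equal(unname(v["v_penetrated_mm3"]), 207, tolerance = 1e-3)
  expect_equal(unname(v["v_increased_mm3"]), 0)
  v2 <- heights_to_volumes(layer_heights(1.03, 0),
                           tube_geometry(radius_mm = 16))
  expect_equal(unname(v2["v_penetrated_mm3"]),
               4 * unname(v["v_penetrated_mm3"]))
})
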