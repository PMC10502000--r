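small_grid <- function() volume_grid(c(48, 48, 48), c(2, 2, 2))

test_that("the same seed reproduces a phantom bit-exactly", {
  a <- generate_phantom(small_grid(), n_tubes = 2, diameter_range = c(8, 20),
                        seed = 4)
  b <- generate_phantom(small_grid(), n_tubes = 2, diameter_range = c(8, 20),
                        seed = 4)
  expect_identical(a$ct, b$ct)
  expect_identical(a$truth_labels$values, b$truth_labels$values)
  expect_identical(a$truth_diameters$values, b$truth_diameters$values)
  c <- generate_phantom(small_grid(), n_tubes = 2, diameter_range = c(8, 20),
                        seed = 5)
  expect_false(identical(a$ct, c$ct))
})

test_that("constant-diameter tubes yield a constant truth diameter map", {
  ph <- make_straight_phantom(diameter = 30, spacing = c(1, 1, 1),
                              length_mm = 80)
  vals <- ph$truth_diameters$values[ph$truth_labels$values != 0L]
  expect_true(length(vals) > 0)
  expect_equal(unique(vals), 30)
})

test_that("a straight tube's labeled volume matches the analytic cylinder", {
  d <- 20; L <- 100
  ph <- make_straight_phantom(diameter = d, length_mm = L, spacing = c(1, 1, 1))
  n_vox <- sum(ph$truth_labels$values != 0L)
  # cylinder plus two half-diameter end caps from the endpoint clamping
  expected <- pi * (d / 2)^2 * L + (4 / 3) * pi * (d / 2)^3
  expect_lt(abs(n_vox - expected) / expected, 0.10)
})

test_that("phantom construction respects its contrast regimen", {
  ph <- generate_phantom(small_grid(), n_tubes = 1, diameter_range = c(10, 24),
                         noise_sd = 0, seed = 9)
  lum <- ph$tubes[[1]]$lumen_hu
  inside <- ph$truth_labels$values != 0L
  expect_true(all(abs(ph$ct[inside] - lum) < 1e-9))
  expect_true(any(abs(ph$ct[!inside] - (-100)) < 1e-9)) # fat background present
})

test_that("tubes that cannot fit the grid raise an error", {
  expect_error(
    generate_phantom(volume_grid(c(16, 16, 16)), diameter_range = c(10, 60),
                     seed = 1),
    "cannot fit")
})

test_that("gaze recording blocks average round(rate * dwell) raw samples", {
  ph <- make_straight_phantom(length_mm = 120, diameter = 12)
  noise <- gaze_noise(jitter_sd = 0, diameter_error_sd = 0,
                      step_along_centerline = 0.2)
  ann <- simulate_gaze_recording(ph, noise, seed = 3)
  s_knots <- gutgaze:::polyline_cumlen(ph$tubes[[1]]$control_points)
  n_raw <- length(seq(0, max(s_knots), by = noise$step_along_centerline))
  m <- round(noise$raw_rate * noise$dwell)
  expect_equal(m, 45L)
  n_full <- n_raw %/% m
  n_rest <- n_raw - n_full * m
  expected_pts <- n_full + as.integer(n_rest >= m / 2)
  expect_equal(nrow(ann), expected_pts)
})

test_that("noiseless recordings of a straight tube sit on the centerline", {
  ph <- make_straight_phantom(length_mm = 150, diameter = 16)
  ann <- simulate_gaze_recording(
    ph, gaze_noise(jitter_sd = 0, diameter_error_sd = 0), seed = 1)
  ctr <- unname(ph$tubes[[1]]$control_points[1, 1:2])
  expect_equal(ann$x, rep(ctr[1], nrow(ann)), tolerance = 1e-9)
  expect_equal(ann$y, rep(ctr[2], nrow(ann)), tolerance = 1e-9)
  expect_equal(unique(ann$diameter), 16) # knob rounding of an exact value
})

test_that("noiseless recordings of curved tubes stay near the centerline", {
  ph <- generate_phantom(small_grid(), n_tubes = 1, diameter_range = c(10, 20),
                         seed = 12)
  ann <- simulate_gaze_recording(
    ph, gaze_noise(jitter_sd = 0, diameter_error_sd = 0), seed = 2)
  tb <- ph$tubes[[1]]
  seg <- tibble::tibble(x = tb$control_points[, 1], y = tb$control_points[, 2],
                        z = tb$control_points[, 3],
                        diameter = tb$diameter_profile)
  dev <- point_to_segment_distance(as.matrix(ann[, c("x", "y", "z")]), seg)
  # chord averaging over 45 samples bends slightly inside curves only
  expect_lt(max(dev$distance), 0.5)
})

test_that("block averaging reduces jitter by sqrt(45)", {
  ph <- make_straight_phantom(length_mm = 156, diameter = 12)
  noise <- gaze_noise(jitter_sd = 2, diameter_error_sd = 0,
                      step_along_centerline = 0.0031)
  ann <- simulate_gaze_recording(ph, noise, seed = 8)
  expect_gt(nrow(ann), 1000)
  ctr <- ph$tubes[[1]]$control_points[1, 1:2]
  sd_eff <- 2 / sqrt(45)
  expected_abs <- sd_eff * sqrt(2 / pi) # mean |N(0, sd_eff)|
  expect_equal(mean(abs(ann$x - ctr[1])), expected_abs, tolerance = 0.2 * expected_abs)
  expect_equal(mean(abs(ann$y - ctr[2])), expected_abs, tolerance = 0.2 * expected_abs)
})

test_that("recorded diameters are knob-quantized and floored", {
  ph <- make_straight_phantom(length_mm = 120, diameter = 11.4)
  ann <- simulate_gaze_recording(
    ph, gaze_noise(jitter_sd = 0, diameter_error_sd = 0, knob_step = 1), seed = 1)
  expect_equal(unique(ann$diameter), 11) # rounded to the knob step
  ann2 <- simulate_gaze_recording(
    ph, gaze_noise(jitter_sd = 0, diameter_error_sd = 50, knob_step = 1), seed = 1)
  expect_true(all(ann2$diameter >= 1)) # floored at one step
  expect_true(all(ann2$diameter == round(ann2$diameter)))
})

test_that("caliper simulation respects axis ordering and en-face geometry", {
  ph <- make_straight_phantom(length_mm = 120, diameter = 18)
  cal0 <- simulate_calipers(ph, n_sites = 6, axis_noise_sd = 0, seed = 2)
  expect_equal(cal0$short_axis, cal0$true_diameter)
  expect_equal(cal0$long_axis, cal0$true_diameter)
  cal <- simulate_calipers(ph, n_sites = 30, axis_noise_sd = 0.1, seed = 3)
  expect_true(all(cal$short_axis <= cal$long_axis))
  expect_true(all(cal$short_axis > 0))
  # a tube along x is never en face to the axial plane
  ph_x <- ph
  ph_x$tubes[[1]]$control_points <- ph$tubes[[1]]$control_points[, c(3, 2, 1)]
  expect_error(simulate_calipers(ph_x, n_sites = 3, seed = 1), "en-face")
})
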