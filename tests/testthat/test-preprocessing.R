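test_that("window/level normalization maps the soft-tissue window to [-1, 1]", {
  expect_equal(window_normalize(40), 0)
  expect_equal(window_normalize(240), 1)
  expect_equal(window_normalize(-160), -1)
  expect_equal(window_normalize(1000), 1) # clipped
  expect_equal(window_normalize(-1000), -1)
  expect_error(window_normalize(0, window = 0), "> 0")
  # monotone non-decreasing in HU
  hu <- sort(runif(200, -1200, 1200))
  expect_true(all(diff(window_normalize(hu)) >= 0))
})

test_that("diameter unit conversion divides by in-plane voxel size", {
  g <- volume_grid(c(6, 6, 3), c(0.75, 0.75, 3.72))
  dm <- diameter_map(array(c(30, rep(0, 107)), c(6, 6, 3)), g, "mm")
  dv <- diameter_to_voxels(dm)
  expect_equal(dv$values[1], 40) # 30 mm at 0.75 mm voxels
  expect_equal(dv$values[2], 0)
  expect_equal(dv$units, "voxels")
  back <- voxels_to_mm(dv)
  expect_equal(back$values, dm$values, tolerance = 1e-9)
  aniso <- diameter_map(array(1, c(4, 4, 2)),
                        volume_grid(c(4, 4, 2), c(0.7, 0.9, 3)), "mm")
  expect_error(diameter_to_voxels(aniso), "isotropic")
  expect_error(diameter_to_voxels(dv), "must be in mm")
})

test_that("sample weights follow the closed-form mean", {
  lab <- array(0L, c(10, 10, 2))
  expect_equal(make_weights(lab), array(1, c(10, 10, 2)))
  lab[3, 4, 1] <- 2L
  w <- make_weights(lab, foreground_weight = 10)
  expect_equal(sum(w == 10), 1L)
  expect_error(make_weights(lab, foreground_weight = 0.5), ">= 1")
  for (s in 1:3) {
    withr::with_seed(s, {
      mask <- array(sample(0:3, 500, TRUE, prob = c(0.8, 0.1, 0.05, 0.05)),
                    c(10, 10, 5))
      fw <- runif(1, 1, 20)
    })
    w <- make_weights(mask, fw)
    frac <- mean(mask != 0L)
    expect_equal(mean(w), 1 + (fw - 1) * frac, tolerance = 1e-12)
  }
})

test_that("model resizing preserves constants, label codes and diameter values", {
  g <- volume_grid(c(16, 16, 4))
  s <- training_sample(array(0.5, g$shape), array(0L, g$shape),
                       array(0, g$shape), array(1, g$shape), g)
  r <- resize_for_model(s, c(8, 8))
  expect_equal(dim(r$image), c(8L, 8L, 4L))
  expect_true(all(abs(r$image - 0.5) < 1e-12)) # constant field survives
  # nearest-neighbor label resize introduces no new codes; diameters untouched
  withr::with_seed(11, {
    lab <- array(sample(c(0L, 2L, 3L), prod(g$shape), TRUE), g$shape)
  })
  dvx <- array(ifelse(lab != 0L, 12.5, 0), g$shape)
  s2 <- training_sample(array(0, g$shape), lab, dvx, make_weights(lab), g)
  r2 <- resize_for_model(s2, c(8, 8))
  expect_true(all(unique(as.vector(r2$labels3)) %in% unique(as.vector(lab))))
  expect_true(all(r2$diam_vox %in% c(0, 12.5)))
})

test_that("the 3d path zero-pads the slice axis to a decimation-friendly count", {
  g <- volume_grid(c(16, 16, 100), c(1, 1, 3.72))
  s <- training_sample(array(0.25, g$shape), array(0L, g$shape),
                       array(0, g$shape), array(1, g$shape), g)
  r <- resize_for_model(s, c(8, 8, 64))
  # 100 slices pad to 128 (next multiple of 64), then decimate by 2
  expect_equal(dim(r$image), c(8L, 8L, 64L))
  expect_equal(r$grid$spacing[3], 128 * 3.72 / 64)
  # padded region carries fill values: image -1, labels 0, weights 1
  expect_true(any(r$image == -1))
  expect_true(all(r$weights == 1))
  r2 <- resize_for_model(s, c(8, 8, 50)) # 100 = 2 x 50, no padding needed
  expect_equal(dim(r2$image)[3], 50L)
  expect_true(all(abs(r2$image - 0.25) < 1e-12))
})

test_that("augmentation parameters respect their ranges and seeds", {
  expect_error(augment_params(translation = c(40, 0)), "30 mm")
  expect_error(augment_params(rotation = c(0, 0, 31)), "30 degrees")
  expect_error(augment_params(magnification = 1.4), "0.7, 1.3")
  a <- random_augment_params(seed = 3)
  b <- random_augment_params(seed = 3)
  expect_identical(a, b)
  expect_true(all(abs(a$translation) <= 30))
  expect_true(all(abs(a$rotation) <= 30))
  expect_true(a$magnification >= 0.7 && a$magnification <= 1.3)
})

make_sphere_sample <- function(grid, radius = 10) {
  ctr <- grid$origin + (grid$shape - 1) / 2 * grid$spacing
  centers <- voxel_centers(grid)
  inside <- sqrt(rowSums(sweep(centers, 2, ctr)^2)) <= radius
  lab <- array(ifelse(inside, 2L, 0L), grid$shape)
  dvx <- array(ifelse(inside, 10, 0), grid$shape)
  training_sample(array(0, grid$shape), lab, dvx, make_weights(lab), grid)
}

test_that("identity augmentation is a no-op and magnification rescales diameters", {
  g <- volume_grid(c(20, 20, 10), c(1, 1, 3))
  s <- make_sphere_sample(g, radius = 7)
  id <- augment(s, augment_params())
  expect_identical(id$labels3, s$labels3)
  expect_identical(id$diam_vox, s$diam_vox)
  expect_identical(id$weights, s$weights)
  mag <- augment(s, augment_params(magnification = 1.2))
  nz <- mag$diam_vox[mag$diam_vox > 0]
  expect_equal(unique(nz), 10 * 1.2) # every non-zero value scaled exactly
  # magnify then shrink restores diameter values on surviving voxels
  undo <- augment(mag, augment_params(magnification = 1 / 1.2))
  surv <- undo$diam_vox > 0 & s$diam_vox > 0
  expect_true(any(surv))
  expect_equal(unique(undo$diam_vox[surv]), 10, tolerance = 1e-6)
})

test_that("rotation on an anisotropic grid preserves spherical shapes", {
  g <- volume_grid(c(40, 40, 16), c(1, 1, 3))
  s <- make_sphere_sample(g, radius = 15)
  rot <- augment(s, augment_params(rotation = c(0, 0, 30)))
  # a centered sphere is invariant under rotation about its center
  expect_gt(dice(rot$labels3 != 0L, s$labels3 != 0L), 0.95)
  rot2 <- augment(s, augment_params(rotation = c(20, 0, 0)))
  expect_gt(dice(rot2$labels3 != 0L, s$labels3 != 0L), 0.95)
})

test_that("translation moves labels by whole-voxel offsets exactly", {
  g <- volume_grid(c(24, 24, 6))
  s <- make_sphere_sample(g, radius = 5)
  tr <- augment(s, augment_params(translation = c(4, 0)))
  expect_equal(sum(tr$labels3 != 0L), sum(s$labels3 != 0L))
  expect_identical(tr$labels3[5:24, , ], s$labels3[1:20, , ])
})
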