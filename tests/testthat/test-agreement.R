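test_that("dice handles the standard overlap cases", {
  m <- array(FALSE, c(4, 4, 2))
  m[1:2, 1:2, 1] <- TRUE
  expect_equal(dice(m, m), 1)
  n <- array(FALSE, c(4, 4, 2))
  n[3:4, 3:4, 2] <- TRUE
  expect_equal(dice(m, n), 0)
  # |A| = |B| = 4, overlap 2
  a <- array(FALSE, c(4, 4, 2)); a[1:4, 1, 1] <- TRUE
  b <- array(FALSE, c(4, 4, 2)); b[3:4, 1, 1] <- TRUE; b[1:2, 2, 1] <- TRUE
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, b), dice(b, a)) # symmetry
  empty <- array(FALSE, c(4, 4, 2))
  expect_true(is.na(dice(empty, empty))) # undefined, excluded downstream
  expect_equal(dice(a, empty), 0)
  expect_error(dice(m, array(FALSE, c(3, 3, 2))), "different grids")
})

test_that("per-part dice distinguishes absence in one vs both", {
  g <- volume_grid(c(6, 6, 1))
  la <- array(0L, g$shape); la[1:2, 1, 1] <- 1L
  lb <- array(0L, g$shape); lb[1:2, 1, 1] <- 1L; lb[4, 4, 1] <- 2L
  d <- dice_by_part(label_volume(la, g, "parts3"), label_volume(lb, g, "parts3"))
  expect_equal(d$dice[d$part == "1"], 1)
  expect_equal(d$dice[d$part == "2"], 0) # present in one only
  expect_true(is.na(d$dice[d$part == "3"])) # absent from both
})

test_that("ICC(A,1) matches examples and is shift-invariant", {
  x <- c(3.1, 4.5, 2.2, 6.6, 5.0, 3.9)
  dup <- data.frame(a = x, b = x)
  r <- icc_two_way_agreement(dup)
  expect_equal(r$icc, 1)
  expect_true(r$ci_low <= r$icc && r$ci_high >= r$icc)
  # shift invariance
  withr::with_seed(8, {
    m <- matrix(rnorm(60), 30, 2)
    m[, 2] <- m[, 1] + rnorm(30, 0.1, 0.4)
  })
  r1 <- icc_two_way_agreement(as.data.frame(m))
  r2 <- icc_two_way_agreement(as.data.frame(m + 100))
  expect_equal(r1$icc, r2$icc, tolerance = 1e-9)
  expect_error(icc_two_way_agreement(m[1:2, ]), "at least 3")
  # degenerate zero-variance input is flagged
  rd <- icc_two_way_agreement(data.frame(a = rep(2, 5), b = rep(2, 5)))
  expect_true(rd$degenerate)
  expect_equal(rd$icc, 1)
})

test_that("ICC(A,1) equals the brute-force ANOVA oracle", {
  for (s in 1:20) {
    withr::with_seed(300 + s, {
      n <- sample(5:40, 1)
      bias <- rnorm(1, 0, 2)
      subj <- rnorm(n, 20, 6)
      x <- cbind(subj + rnorm(n), subj + bias + rnorm(n))
    })
    expect_equal(icc_two_way_agreement(as.data.frame(x))$icc,
                 icc_a1_oracle(x), tolerance = 1e-10)
  }
})

test_that("ICC of independent ratings is near zero", {
  withr::with_seed(99, {
    x <- matrix(rnorm(20000), 10000, 2)
  })
  r <- icc_two_way_agreement(as.data.frame(x))
  expect_lt(abs(r$icc), 0.05)
})

test_that("limits of agreement recover bias and half-width", {
  d <- data.frame(a = c(13, 22, 31), b = c(10, 19, 28))
  r <- limits_of_agreement(d, a, b)
  expect_equal(r$bias, 3)
  expect_equal(r$loa_halfwidth, 0)
  same <- data.frame(a = c(1, 2, 5), b = c(1, 2, 5))
  r0 <- limits_of_agreement(same, a, b)
  expect_equal(r0$bias, 0)
  expect_equal(r0$loa_halfwidth, 0)
  # antisymmetry of the bias, symmetry of the half-width
  withr::with_seed(12, {
    dd <- data.frame(a = rnorm(50, 10, 2), b = rnorm(50, 9, 2))
  })
  fwd <- limits_of_agreement(dd, a, b)
  rev <- limits_of_agreement(dd, b, a)
  expect_equal(fwd$bias, -rev$bias)
  expect_equal(fwd$loa_halfwidth, rev$loa_halfwidth)
  expect_error(limits_of_agreement(dd[1, ], a, b), "at least 2")
})

test_that("diameter maps are sampled at world locations with masked search", {
  ph <- make_straight_phantom(length_mm = 60, diameter = 30,
                              spacing = c(1, 1, 1))
  ctr <- ph$tubes[[1]]$control_points[1, ]
  mid <- c(ctr[1], ctr[2], 30)
  s <- sample_diameter_at(ph$truth_diameters,
                          tibble::tibble(x = mid[1], y = mid[2], z = mid[3]))
  expect_equal(s$diameter, 30)
  # a site just outside the masked tube resolves to the nearest non-zero voxel
  outside <- tibble::tibble(x = mid[1] + 16.2, y = mid[2], z = mid[3])
  s2 <- sample_diameter_at(ph$truth_diameters, outside, search_radius = 5)
  expect_equal(s2$diameter, 30)
  expect_error(sample_diameter_at(ph$truth_diameters,
                                  tibble::tibble(x = -500, y = 0, z = 0)),
               "outside the grid")
  far <- tibble::tibble(x = ph$grid$origin[1], y = ph$grid$origin[2], z = 1)
  expect_error(sample_diameter_at(ph$truth_diameters, far, search_radius = 1),
               "non-zero")
  # dense maps sample the nearest voxel directly
  dense <- diameter_map(array(7, ph$grid$shape), ph$grid, "mm", masked = FALSE)
  expect_equal(sample_diameter_at(dense, outside)$diameter, 7)
})

test_that("caliper pairing offers mean, short and long manual values", {
  ph <- make_straight_phantom(length_mm = 80, diameter = 24)
  cal <- simulate_calipers(ph, n_sites = 5, axis_noise_sd = 0.1, seed = 4)
  pm <- pair_calipers_with_map(cal, ph$truth_diameters)
  expect_equal(pm$manual, (cal$short_axis + cal$long_axis) / 2)
  expect_equal(pm$mapped, rep(24, 5))
  ps <- pair_calipers_with_map(cal, ph$truth_diameters, value = "short")
  expect_equal(ps$manual, cal$short_axis)
})

test_that("comparing a source with itself yields perfect agreement", {
  ph <- generate_phantom(volume_grid(c(40, 40, 40), c(2, 2, 2)), n_tubes = 2,
                         diameter_range = c(8, 18), seed = 21)
  src <- list(labels = ph$truth_labels, diameters = ph$truth_diameters)
  cal <- simulate_calipers(ph, n_sites = 6, axis_noise_sd = 0, seed = 5)
  rep_ <- compare_sources(list(p = src), list(p = src),
                          sites = dplyr::mutate(cal, scan_id = "p"))
  expect_true(all(rep_$dice$mean == 1))
  expect_equal(rep_$icc$icc, 1)
  expect_equal(rep_$loa$bias, 0)
  expect_equal(rep_$loa$loa_halfwidth, 0)
  g <- glance(rep_)
  expect_equal(g$dice_all, 1)
  td <- tidy(rep_)
  expect_true(all(c("dice", "icc", "bias", "loa_halfwidth") %in% td$metric))
})

test_that("parts empty in both sources are excluded from their Dice n", {
  g <- volume_grid(c(8, 8, 1))
  mk <- function(vals) list(
    labels = label_volume(vals, g, "parts13"),
    diameters = diameter_map(array(0, g$shape), g, "mm"))
  la <- array(0L, g$shape); la[1:3, 1, 1] <- 4L # midgut only
  lb <- array(0L, g$shape); lb[1:2, 1, 1] <- 4L
  rep_ <- compare_sources(list(s = mk(la)), list(s = mk(lb)))
  expect_setequal(rep_$dice$part, c("all", "2")) # foregut/hindgut dropped
  expect_equal(rep_$dice$mean[rep_$dice$part == "2"], 2 * 2 / (3 + 2))
  # empty in one counts as zero under the default rule
  lc <- array(0L, g$shape); lc[5, 5, 1] <- 1L
  rep2 <- compare_sources(list(s = mk(la)), list(s = mk(lc)))
  expect_equal(rep2$dice$mean[rep2$dice$part == "1"], 0)
  expect_equal(rep2$dice$mean[rep2$dice$part == "2"], 0)
  # ... and is dropped entirely under the "either" rule
  rep3 <- compare_sources(list(s = mk(la)), list(s = mk(lc)),
                          exclusion = "either")
  expect_setequal(rep3$dice$part, "all")
})

test_that("two noisy repetitions produce a complete, intermediate report", {
  g <- volume_grid(c(40, 40, 40), c(2.4, 2.4, 2.4))
  srcs <- lapply(1:2, function(rep_i) {
    lapply(1:2, function(i) {
      ph <- generate_phantom(g, n_tubes = 1, diameter_range = c(10, 24),
                             seed = 40 + i)
      rec <- reconstruct(simulate_gaze_recording(
        ph, gaze_noise(jitter_sd = 1), rep_i, seed = 100 * rep_i + i), g)
      list(labels = rec$labels, diameters = rec$diameters)
    })
  })
  names(srcs[[1]]) <- names(srcs[[2]]) <- c("a", "b")
  rep_ <- compare_sources(srcs[[1]], srcs[[2]])
  all_dice <- rep_$dice$mean[rep_$dice$part == "all"]
  expect_gt(all_dice, 0)
  expect_lt(all_dice, 1)
})
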