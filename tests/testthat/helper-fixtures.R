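# Shared fixture builders; everything is generated in code at test time.

# a small two-segment annotation with varied diameters
make_test_annotation <- function(seed = 42, n_segments = 2, n_points = 3,
                                 box = 20) {
  withr::with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(n_segments), function(s) {
      tibble::tibble(
        segment = s, label = sample(1:13, 1),
        x = runif(n_points, 0, box), y = runif(n_points, 0, box),
        z = runif(n_points, 0, box),
        diameter = runif(n_points, 3, 8)
      )
    }))
    scan_annotation(pts, scan_id = paste0("t", seed))
  })
}

# minimal phantom with a single straight tube along z (exact geometry for
# noiseless gaze tests); truth derived by the reconstruction contract
make_straight_phantom <- function(length_mm = 120, diameter = 12,
                                  spacing = c(1, 1, 1)) {
  nz <- ceiling(length_mm / spacing[3]) + 20
  n_xy <- ceiling((diameter + 16) / spacing[1])
  grid <- volume_grid(c(n_xy, n_xy, nz), spacing)
  ctr <- grid$origin[1:2] + (grid$shape[1:2] - 1) / 2 * spacing[1:2]
  z <- seq(5, 5 + length_mm, by = 4)
  P <- cbind(ctr[1], ctr[2], z)
  tube <- list(control_points = P,
               diameter_profile = rep(diameter, nrow(P)),
               label = 4L, lumen_hu = -1000, wall_hu = 40)
  ann <- scan_annotation(tibble::tibble(
    segment = 1L, label = 4L, x = P[, 1], y = P[, 2], z = P[, 3],
    diameter = diameter))
  rec <- reconstruct(ann, grid)
  structure(list(
    ct = array(0, grid$shape), grid = grid,
    truth_labels = rec$labels, truth_diameters = rec$diameters,
    tubes = list(tube), scan_id = "straight",
    params = list()
  ), class = "phantom_volume")
}

# 8 single-slice training samples cut from a small two-tube phantom,
# ordered by foreground content (the richest slices first)
make_training_slices <- function(seed = 7, n_slices = 8) {
  g <- volume_grid(c(64, 64, 24), c(1.5, 1.5, 2.5))
  ph <- generate_phantom(g, n_tubes = 2, diameter_range = c(8, 20), seed = seed)
  smp <- prepare_sample(ph$ct, ph$truth_labels, ph$truth_diameters)
  fg <- vapply(seq_len(g$shape[3]), function(k) mean(smp$labels3[, , k] != 0), 0)
  ks <- order(fg, decreasing = TRUE)[seq_len(n_slices)]
  sg <- volume_grid(c(64, 64, 1), g$spacing, g$origin)
  lapply(ks, function(k) training_sample(
    array(smp$image[, , k], sg$shape),
    array(smp$labels3[, , k], sg$shape),
    array(smp$diam_vox[, , k], sg$shape),
    array(smp$weights[, , k], sg$shape), sg))
}

# independently coded ICC(A,1) oracle via stats::aov sums of squares
icc_a1_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- stats::anova(stats::aov(y ~ subj + rater, data = df))
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
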