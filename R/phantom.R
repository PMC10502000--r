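#' Gaze recording noise model
#'
#' Parameters of the simulated eye-tracker recording. The tracker produces raw
#' samples at `raw_rate` Hz which are averaged over `dwell`-second intervals
#' into gaze points (the defaults, 60 Hz and 0.75 s, give
#' `round(60 * 0.75) = 45` raw samples per gaze point). `jitter_sd` is the
#' isotropic per-axis standard deviation of raw gaze error in mm;
#' `diameter_error_sd` is the error of the annotator's diameter setting, which
#' is quantized to the rotary-knob step `knob_step` (mm) and floored at one
#' step. `step_along_centerline` is the distance in mm the simulated gaze
#' advances along the bowel centerline per raw sample; the default 0.155 mm
#' yields roughly 7 mm between consecutive gaze points, matching observed
#' per-segment gaze spacing (about 97.5 mm traced per 14.3 gaze points).
#'
#' @param jitter_sd,diameter_error_sd,knob_step,step_along_centerline mm.
#' @param raw_rate Hz. @param dwell seconds.
#' @return A list of class `gaze_noise`.
#' @export
gaze_noise <- function(jitter_sd = 1, diameter_error_sd = 1, knob_step = 1,
                       raw_rate = 60, dwell = 0.75,
                       step_along_centerline = 0.155) {
  vals <- c(jitter_sd, diameter_error_sd, knob_step, raw_rate, dwell,
            step_along_centerline)
  if (any(!is.finite(vals)) || any(vals < 0)) abort("All noise parameters must be >= 0.")
  if (raw_rate * dwell < 1) abort("`raw_rate * dwell` must be >= 1 raw sample per gaze point.")
  if (step_along_centerline <= 0) abort("`step_along_centerline` must be > 0.")
  structure(list(
    jitter_sd = jitter_sd, diameter_error_sd = diameter_error_sd,
    knob_step = knob_step, raw_rate = raw_rate, dwell = dwell,
    step_along_centerline = step_along_centerline
  ), class = "gaze_noise")
}

polyline_cumlen <- function(P) {
  if (nrow(P) < 2L) return(0)
  c(0, cumsum(sqrt(rowSums((P[-1L, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))))
}

# linear interpolation of columns of `vals` along arc length
polyline_interp <- function(s_knots, vals, s) {
  vals <- as.matrix(vals)
  out <- matrix(0, length(s), ncol(vals))
  for (j in seq_len(ncol(vals))) {
    out[, j] <- approx(s_knots, vals[, j], xout = s, rule = 2)$y
  }
  out
}

# Smoothed random-walk centerline kept inside a safety box.
random_centerline <- function(lo, hi, margin, step = 4, n_steps) {
  pos <- runif(3, lo + margin, hi - margin)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  P <- matrix(0, n_steps + 1L, 3L)
  P[1L, ] <- pos
  for (i in seq_len(n_steps)) {
    dir <- dir + 0.25 * rnorm(3)
    # steer back toward the interior when close to the walls
    low_push <- pmax(0, (lo + margin + step) - pos) / step
    high_push <- pmax(0, pos - (hi - margin - step)) / step
    dir <- dir + 0.8 * (low_push - high_push)
    dir <- dir / sqrt(sum(dir^2))
    pos <- pos + step * dir
    pos <- pmin(pmax(pos, lo + margin), hi - margin)
    P[i + 1L, ] <- pos
  }
  # moving-average smoothing keeps curvature radii large relative to gaze spacing
  k <- 7L
  if (nrow(P) > k) {
    sm <- apply(P, 2L, function(col) stats::filter(col, rep(1 / k, k), sides = 2))
    keep <- !is.na(sm[, 1L])
    P <- sm[keep, , drop = FALSE]
  }
  pmin(pmax(P, rep(lo + margin, each = nrow(P))), rep(hi - margin, each = nrow(P)))
}

# slowly varying diameter profile within [dmin, dmax]
random_diameter_profile <- function(n, dmin, dmax) {
  d0 <- runif(1, dmin + 0.25 * (dmax - dmin), dmax - 0.25 * (dmax - dmin))
  amp <- runif(1, 0, 0.8 * min(d0 - dmin, dmax - d0))
  cycles <- runif(1, 0.5, 1.5)
  phase <- runif(1, 0, 2 * pi)
  t <- seq(0, 1, length.out = n)
  pmin(pmax(d0 + amp * sin(2 * pi * cycles * t + phase), dmin), dmax)
}

tubes_to_annotation <- function(tubes, scan_id, repetition = 1L, inflate = 0) {
  pts <- purrr::imap_dfr(tubes, function(tb, i) {
    tibble::tibble(
      segment = as.integer(i), label = tb$label,
      x = tb$control_points[, 1L], y = tb$control_points[, 2L],
      z = tb$control_points[, 3L],
      diameter = tb$diameter_profile + inflate
    )
  })
  scan_annotation(pts, scan_id = scan_id, repetition = repetition)
}

#' Generate a synthetic CT phantom with known tubular ground truth
#'
#' Builds a CT-like volume emulating the contrast regime of an unprepared
#' abdomen: fat background (about -100 HU) with soft-tissue regions (about
#' 40 HU), bowel walls at soft-tissue attenuation, lumens of either gas
#' (about -1000 HU) or fluid (about 10 HU), plus additive Gaussian noise.
#' Tubes follow smooth random-walk centerlines with slowly varying diameters
#' drawn from `diameter_range`; tubes are rejection-sampled so they do not
#' overlap, keeping the ground truth unambiguous. Truth labels and the truth
#' diameter map are derived from the exact centerlines by the same
#' nearest-segment contract as [reconstruct()].
#'
#' @param grid A [volume_grid()].
#' @param n_tubes Number of tubes.
#' @param diameter_range Range of tube diameters, mm (default 10--60,
#'   spanning normal to clearly dilated bowel).
#' @param intensities Named list of HU values: `fat`, `soft_tissue`, `wall`,
#'   `gas`, `fluid`.
#' @param noise_sd Additive Gaussian noise, HU.
#' @param wall_thickness Bowel wall thickness, mm.
#' @param n_soft_blobs Number of soft-tissue background ellipsoids.
#' @param labels Optional integer vector of 13-part codes, one per tube;
#'   defaults to distinct bowel parts.
#' @param seed Integer seed; the same seed reproduces the phantom bit-exactly.
#' @return An object of class `phantom_volume`: list with `ct` (HU array),
#'   `grid`, `truth_labels` ([label_volume()]), `truth_diameters`
#'   ([diameter_map()], mm, masked), `tubes` (list of tube specs with
#'   `control_points`, `diameter_profile`, `label`, `lumen_hu`), `scan_id`.
#' @export
generate_phantom <- function(grid, n_tubes = 3, diameter_range = c(10, 60),
                             intensities = list(fat = -100, soft_tissue = 40,
                                                wall = 40, gas = -1000, fluid = 10),
                             noise_sd = 15, wall_thickness = 3,
                             n_soft_blobs = 3, labels = NULL, seed = 1L) {
  stopifnot(inherits(grid, "volume_grid"))
  if (diameter_range[1] <= 0 || diameter_range[2] < diameter_range[1]) {
    abort("`diameter_range` must be positive and increasing.")
  }
  extent <- grid$shape * grid$spacing
  margin <- diameter_range[2] / 2 + wall_thickness + 2
  if (any(extent < 2 * margin + 8)) {
    abort(sprintf(
      "Tubes of diameter up to %.1f mm cannot fit a grid of extent %s mm.",
      diameter_range[2], paste(round(extent, 1), collapse = " x ")))
  }
  if (is.null(labels)) {
    pool <- c(4L, 5L, 8L, 9L, 10L, 11L, 6L, 2L, 3L, 12L)
    labels <- pool[((seq_len(n_tubes) - 1L) %% length(pool)) + 1L]
  }
  stopifnot(length(labels) == n_tubes, all(labels %in% 1:13))
  withr::local_seed(seed)

  lo <- grid$origin - grid$spacing / 2
  hi <- lo + extent
  n_steps <- max(10L, round(1.2 * max(extent) / 4))
  tubes <- list()
  for (i in seq_len(n_tubes)) {
    ok <- FALSE
    for (try in 1:100) {
      P <- random_centerline(lo, hi, margin, step = 4, n_steps = n_steps)
      d <- random_diameter_profile(nrow(P), diameter_range[1], diameter_range[2])
      clearance <- TRUE
      for (tb in tubes) {
        r <- segment_min_d2(P[, 1L], P[, 2L], P[, 3L], tb$control_points,
                            tb$diameter_profile, mode = "polyline")
        need <- (max(d) + max(tb$diameter_profile)) / 2 + 2 * wall_thickness + 1
        if (min(sqrt(r$d2)) < need) { clearance <- FALSE; break }
      }
      if (clearance) { ok <- TRUE; break }
    }
    if (!ok) abort("Could not place non-overlapping tubes in this grid; reduce n_tubes or diameters.")
    tubes[[i]] <- list(
      control_points = P, diameter_profile = d, label = labels[i],
      lumen_hu = if (runif(1) < 0.5) intensities$gas else intensities$fluid,
      wall_hu = intensities$wall
    )
  }

  scan_id <- paste0("phantom-", seed)
  ann <- tubes_to_annotation(tubes, scan_id)
  ann_outer <- tubes_to_annotation(tubes, scan_id, inflate = 2 * wall_thickness)
  rec <- reconstruct(ann, grid, mode = "polyline", masked_diameter = TRUE)
  rec_outer <- reconstruct(ann_outer, grid, mode = "polyline", masked_diameter = TRUE)

  n <- prod(grid$shape)
  ct <- rep(intensities$fat, n)
  centers <- voxel_centers(grid)
  for (b in seq_len(n_soft_blobs)) {
    c0 <- runif(3, lo + 0.1 * extent, hi - 0.1 * extent)
    rr <- runif(3, 0.08, 0.25) * extent
    inside <- ((centers[, 1L] - c0[1]) / rr[1])^2 +
      ((centers[, 2L] - c0[2]) / rr[2])^2 +
      ((centers[, 3L] - c0[3]) / rr[3])^2 <= 1
    ct[inside] <- intensities$soft_tissue
  }
  wall_vox <- rec_outer$segment_index != 0L
  ct[wall_vox] <- intensities$wall
  lumen_idx <- rec$segment_index
  lumen_hu <- vapply(tubes, function(tb) tb$lumen_hu, 0)
  inside_lumen <- lumen_idx != 0L
  ct[inside_lumen] <- lumen_hu[lumen_idx[inside_lumen]]
  ct <- ct + rnorm(n, 0, noise_sd)
  dim(ct) <- grid$shape

  structure(list(
    ct = ct, grid = grid, truth_labels = rec$labels,
    truth_diameters = rec$diameters, tubes = tubes, scan_id = scan_id,
    params = list(diameter_range = diameter_range, noise_sd = noise_sd,
                  wall_thickness = wall_thickness, intensities = intensities,
                  seed = seed)
  ), class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("<phantom_volume> %s @ %s mm, %d tube(s), %d bowel voxel(s)\n",
              paste(x$grid$shape, collapse = "x"),
              paste(format(x$grid$spacing), collapse = "x"),
              length(x$tubes), sum(x$truth_labels$values != 0L)))
  invisible(x)
}

#' Simulate a noisy gaze recording of a phantom
#'
#' Emulates eye-tracked annotation of the phantom's tubes. Raw samples march
#' along each true centerline every `step_along_centerline` mm with isotropic
#' Gaussian jitter; consecutive blocks of `round(raw_rate * dwell)` raw
#' samples (45 at the defaults) are averaged into one gaze point. The recorded
#' diameter is the true local diameter plus Gaussian error, rounded to the
#' knob step and floored at one step. A trailing partial block is kept as a
#' final gaze point if it has at least half a block of samples (so short
#' segments are never empty), and dropped otherwise.
#'
#' @param phantom A [generate_phantom()] result.
#' @param noise A [gaze_noise()] model.
#' @param repetition Annotation repetition (1 or 2).
#' @param seed Integer seed.
#' @return A [scan_annotation()]: one segment per tube, in tube order.
#' @export
simulate_gaze_recording <- function(phantom, noise = gaze_noise(),
                                    repetition = 1L, seed = 1L) {
  stopifnot(inherits(phantom, "phantom_volume"), inherits(noise, "gaze_noise"))
  withr::local_seed(seed)
  m <- round(noise$raw_rate * noise$dwell)
  pts <- purrr::imap_dfr(phantom$tubes, function(tb, i) {
    P <- tb$control_points
    s_knots <- polyline_cumlen(P)
    L <- s_knots[length(s_knots)]
    s <- seq(0, L, by = noise$step_along_centerline)
    raw <- polyline_interp(s_knots, P, s)
    # draw unit normals and scale so the same seed yields the same underlying
    # noise field at every jitter level (common random numbers)
    raw <- raw + matrix(rnorm(length(raw)), nrow(raw), 3L) * noise$jitter_sd
    block <- (seq_along(s) - 1L) %/% m + 1L
    counts <- tabulate(block)
    n_blocks <- length(counts)
    if (n_blocks > 1L && counts[n_blocks] < m / 2) {
      keep <- block <= n_blocks - 1L
      raw <- raw[keep, , drop = FALSE]
      s <- s[keep]
      block <- block[keep]
      n_blocks <- n_blocks - 1L
    }
    counts <- tabulate(block)
    gx <- rowsum(raw, block) / counts
    s_mid <- as.vector(rowsum(matrix(s, ncol = 1), block)) / counts
    d_true <- polyline_interp(s_knots, matrix(tb$diameter_profile, ncol = 1), s_mid)[, 1L]
    d_rec <- d_true + rnorm(n_blocks) * noise$diameter_error_sd
    if (noise$knob_step > 0) {
      d_rec <- pmax(round(d_rec / noise$knob_step) * noise$knob_step, noise$knob_step)
    } else {
      d_rec <- pmax(d_rec, 1e-6)
    }
    tibble::tibble(segment = as.integer(i), label = tb$label,
                   x = gx[, 1L], y = gx[, 2L], z = gx[, 3L], diameter = d_rec)
  })
  scan_annotation(pts, scan_id = phantom$scan_id, repetition = repetition)
}

#' Simulate manual caliper measurements on a phantom
#'
#' Picks random centerline sites where the tube runs within `max_angle`
#' degrees of the z-axis (i.e. the bowel is en face to the axial plane, so its
#' true cross-section lies in-plane) and places a short-axis/long-axis caliper
#' pair there. Each axis is the true diameter perturbed multiplicatively:
#' `long = d * (1 + |e1|)`, `short = d * (1 - |e2|)` with
#' `e ~ N(0, axis_noise_sd)`; short <= long is enforced by swapping.
#'
#' @param phantom A [generate_phantom()] result.
#' @param n_sites Number of caliper sites.
#' @param axis_noise_sd Relative axis error standard deviation.
#' @param max_angle Maximal angle (degrees) between tube tangent and z-axis.
#' @param seed Integer seed.
#' @return A tibble: `scan_id`, `site`, `label`, `x`, `y`, `z`, `short_axis`,
#'   `long_axis`, `true_diameter` (all mm).
#' @export
simulate_calipers <- function(phantom, n_sites = 10, axis_noise_sd = 0.05,
                              max_angle = 30, seed = 1L) {
  stopifnot(inherits(phantom, "phantom_volume"))
  if (length(phantom$tubes) == 0L) abort("Phantom has no tubes.")
  withr::local_seed(seed)
  cos_max <- cos(max_angle * pi / 180)
  out <- vector("list", n_sites)
  attempts <- 0L
  max_attempts <- 400L * n_sites
  found <- 0L
  while (found < n_sites && attempts < max_attempts) {
    attempts <- attempts + 1L
    tb <- phantom$tubes[[sample.int(length(phantom$tubes), 1L)]]
    P <- tb$control_points
    s_knots <- polyline_cumlen(P)
    L <- s_knots[length(s_knots)]
    s <- runif(1, 0, L)
    j <- max(1L, findInterval(s, s_knots, rightmost.closed = TRUE))
    tangent <- P[min(j + 1L, nrow(P)), ] - P[j, ]
    nt <- sqrt(sum(tangent^2))
    if (nt == 0) next
    if (abs(tangent[3L]) / nt < cos_max) next
    loc <- polyline_interp(s_knots, P, s)[1L, ]
    d <- polyline_interp(s_knots, matrix(tb$diameter_profile, ncol = 1), s)[1L, 1L]
    long <- d * (1 + abs(rnorm(1, 0, axis_noise_sd)))
    short <- d * (1 - abs(rnorm(1, 0, axis_noise_sd)))
    if (short > long) { tmp <- short; short <- long; long <- tmp }
    found <- found + 1L
    out[[found]] <- tibble::tibble(
      scan_id = phantom$scan_id, site = found, label = tb$label,
      x = loc[1L], y = loc[2L], z = loc[3L],
      short_axis = short, long_axis = long, true_diameter = d
    )
  }
  if (found == 0L) abort("No en-face site found on any tube.")
  if (found < n_sites) {
    warn_msg <- sprintf("Only %d of %d requested en-face sites found.", found, n_sites)
    rlang::warn(warn_msg)
  }
  dplyr::bind_rows(out[seq_len(found)])
}
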