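#' Window/level normalization of CT intensities
#'
#' Maps Hounsfield units into \[-1, 1\] with standard window/level semantics:
#' `clip(2 * (v - level) / window, -1, 1)`. The defaults (window 400 HU,
#' level 40 HU) are a soft-tissue window: 40 HU maps to 0, the window edges
#' -160 and 240 HU map to -1 and 1, values beyond the window are clipped.
#'
#' @param ct Numeric array or vector of HU values.
#' @param window Window width in HU (> 0).
#' @param level Window center in HU.
#' @return Same shape as `ct`, values in \[-1, 1\].
#' @examples
#' window_normalize(c(-1000, 40, 240))
#' @export
window_normalize <- function(ct, window = 400, level = 40) {
  if (!is.numeric(window) || window <= 0) abort("`window` must be > 0.")
  pmin(pmax(2 * (ct - level) / window, -1), 1)
}

#' Convert a diameter map between millimetres and voxel units
#'
#' Diameters are learned in voxel units so that the varying field of view of
#' CT scans (and of patients) does not confound the regression: a value in
#' voxels is consistent across scans and converts back to mm by multiplying
#' with the known voxel size. Conversion uses the in-plane voxel size only
#' (calipers and gaze ROIs live in the axial plane; slice thickness is not a
#' natural diameter unit), so in-plane spacing must be isotropic.
#'
#' @param diam A [diameter_map()] in mm (`diameter_to_voxels`) or in voxels
#'   (`voxels_to_mm`).
#' @return A [diameter_map()] in the other unit.
#' @export
diameter_to_voxels <- function(diam) {
  stopifnot(inherits(diam, "diameter_map"))
  if (diam$units != "mm") abort("`diam` must be in mm.")
  sp <- diam$grid$spacing
  if (abs(sp[1L] - sp[2L]) > 1e-6) {
    abort("In-plane voxel spacing must be isotropic (x == y) to express diameters in voxels.")
  }
  diameter_map(diam$values / sp[1L], diam$grid, units = "voxels", masked = diam$masked)
}

#' @rdname diameter_to_voxels
#' @export
voxels_to_mm <- function(diam) {
  stopifnot(inherits(diam, "diameter_map"))
  if (diam$units != "voxels") abort("`diam` must be in voxels.")
  sp <- diam$grid$spacing
  if (abs(sp[1L] - sp[2L]) > 1e-6) {
    abort("In-plane voxel spacing must be isotropic (x == y).")
  }
  diameter_map(diam$values * sp[1L], diam$grid, units = "mm", masked = diam$masked)
}

#' Per-voxel sample weights from a label volume
#'
#' Bowel voxels are a small minority of an abdominal CT volume; a sample
#' weight increases the contribution of all non-background voxels to the
#' training loss so the network does not collapse to predicting background.
#'
#' @param labels3 Integer array of 3-part labels (or a [label_volume()]).
#' @param foreground_weight Weight for non-background voxels (>= 1);
#'   background voxels get weight 1.
#' @return Numeric array of weights, same shape as the labels.
#' @export
make_weights <- function(labels3, foreground_weight = 10) {
  if (foreground_weight < 1) abort("`foreground_weight` must be >= 1.")
  v <- if (inherits(labels3, "label_volume")) labels3$values else labels3
  w <- ifelse(v != 0L, foreground_weight, 1)
  if (!is.null(dim(v))) dim(w) <- dim(v)
  w
}

#' Assemble a model-ready training sample
#'
#' Bundles the four aligned channels the network consumes: the window/level
#' normalized image, the 3-part label volume, the diameter map in voxel units,
#' and the per-voxel sample weights.
#'
#' @param image Normalized array in \[-1, 1\].
#' @param labels3 Integer array, codes 0..3.
#' @param diam_vox Numeric array of diameters in voxel units, >= 0.
#' @param weights Numeric array of weights, > 0; defaults to
#'   [make_weights()] of `labels3`.
#' @param grid The shared [volume_grid()].
#' @return An object of class `training_sample`.
#' @export
training_sample <- function(image, labels3, diam_vox, weights = NULL, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.null(weights)) weights <- make_weights(labels3)
  dims <- list(dim(image), dim(labels3), dim(diam_vox), dim(weights))
  if (!all(vapply(dims, function(d) identical(as.integer(d), grid$shape), TRUE))) {
    abort("All channels must share `grid$shape`.")
  }
  if (min(image) < -1 - 1e-9 || max(image) > 1 + 1e-9) abort("`image` must lie in [-1, 1].")
  if (min(diam_vox) < 0) abort("`diam_vox` must be >= 0.")
  if (min(weights) <= 0) abort("`weights` must be > 0.")
  structure(list(image = image, labels3 = labels3, diam_vox = diam_vox,
                 weights = weights, grid = grid), class = "training_sample")
}

#' Prepare a training sample from raw volumes
#'
#' Applies the full normalization chain: window/level scaling of the CT,
#' 13-part to 3-part label reduction, mm-to-voxel diameter conversion, and
#' foreground sample weighting.
#'
#' @param ct HU array on `labels$grid`.
#' @param labels A [label_volume()] (13- or 3-part).
#' @param diameters A [diameter_map()] in mm.
#' @param window,level Window/level in HU (defaults 400/40).
#' @param foreground_weight Weight of non-background voxels (default 10).
#' @return A [training_sample()].
#' @export
prepare_sample <- function(ct, labels, diameters, window = 400, level = 40,
                           foreground_weight = 10) {
  stopifnot(inherits(labels, "label_volume"), inherits(diameters, "diameter_map"))
  lab3 <- reduce_label_volume(labels)
  dvox <- if (diameters$units == "mm") diameter_to_voxels(diameters) else diameters
  training_sample(
    image = window_normalize(ct, window, level),
    labels3 = lab3$values,
    diam_vox = dvox$values,
    weights = make_weights(lab3$values, foreground_weight),
    grid = labels$grid
  )
}

#' Resize a training sample to the model input shape
#'
#' For the 2d model, slices are resized in-plane (e.g. 512 x 512 to
#' 256 x 256). For the 3d model, the slice axis is first padded to the next
#' multiple of the target slice count (image padded with -1, labels and
#' diameters with 0, weights with 1) and then decimated by the resulting
#' integer factor, so no interpolation happens along z; in-plane axes are then
#' resized. The image channel is linearly interpolated; labels, diameters and
#' weights use nearest-neighbor so no new label codes appear. Diameter
#' *values* are untouched: they count voxels of the original scan and remain
#' valid descriptors of physical bowel caliber via the original spacing.
#'
#' @param sample A [training_sample()].
#' @param target Length 2 (per-slice, e.g. `c(256, 256)`) or length 3
#'   (volume, e.g. `c(128, 128, 64)`).
#' @return A [training_sample()] on the resized grid.
#' @export
resize_for_model <- function(sample, target = c(256, 256)) {
  stopifnot(inherits(sample, "training_sample"))
  grid <- sample$grid
  shp <- grid$shape
  target <- as.integer(target)
  if (!length(target) %in% c(2L, 3L)) abort("`target` must have length 2 or 3.")

  img <- sample$image; lab <- sample$labels3
  dvx <- sample$diam_vox; wts <- sample$weights
  if (length(target) == 3L) {
    nz <- shp[3L]
    padded <- as.integer(ceiling(nz / target[3L]) * target[3L])
    if (padded > nz) {
      pad_block <- function(a, fill) {
        out <- array(fill, c(shp[1L], shp[2L], padded))
        out[, , seq_len(nz)] <- a
        out
      }
      img <- pad_block(img, -1)
      lab <- pad_block(lab, 0L)
      dvx <- pad_block(dvx, 0)
      wts <- pad_block(wts, 1)
    }
    if (padded %% target[3L] != 0L) abort("Padded slice count must be a multiple of the z target.")
    new_shape <- target
    img <- resize_array(img, new_shape, method = c("linear", "linear", "nearest"))
    lab <- resize_array(lab, new_shape, method = "nearest")
    dvx <- resize_array(dvx, new_shape, method = "nearest")
    wts <- resize_array(wts, new_shape, method = "nearest")
    extent <- c(shp[1L], shp[2L], padded) * grid$spacing
  } else {
    new_shape <- c(target, shp[3L])
    img <- resize_array(img, new_shape, method = c("linear", "linear", "nearest"))
    lab <- resize_array(lab, new_shape, method = "nearest")
    dvx <- resize_array(dvx, new_shape, method = "nearest")
    wts <- resize_array(wts, new_shape, method = "nearest")
    extent <- shp * grid$spacing
  }
  new_spacing <- extent / new_shape
  new_origin <- grid$origin + (new_spacing - grid$spacing * c(1, 1, 1)) / 2
  new_grid <- volume_grid(new_shape, new_spacing, new_origin)
  training_sample(img, array(as.integer(lab), new_shape), dvx, wts, new_grid)
}

#' Geometric augmentation parameters
#'
#' In-plane translations up to +/- 30 mm, rotations up to +/- 30 degrees
#' about each axis, and magnification within 0.7--1.3 (i.e. +/- 30%). The
#' transform is composed in physical mm space (translate after rotate after
#' scale, about the volume center), so geometry is preserved despite voxel
#' anisotropy.
#'
#' @param translation `c(tx, ty)` mm, each within +/- 30.
#' @param rotation `c(rx, ry, rz)` degrees, each within +/- 30.
#' @param magnification Scalar in \[0.7, 1.3\].
#' @return A list of class `augment_params`.
#' @export
augment_params <- function(translation = c(0, 0), rotation = c(0, 0, 0),
                           magnification = 1) {
  if (length(translation) != 2L || any(abs(translation) > 30)) {
    abort("`translation` must be c(tx, ty) within +/- 30 mm.")
  }
  if (length(rotation) != 3L || any(abs(rotation) > 30)) {
    abort("`rotation` must be c(rx, ry, rz) within +/- 30 degrees.")
  }
  if (magnification < 0.7 || magnification > 1.3) {
    abort("`magnification` must lie in [0.7, 1.3].")
  }
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 magnification = as.numeric(magnification)),
            class = "augment_params")
}

#' @rdname augment_params
#' @param seed Integer seed for the uniform draws.
#' @export
random_augment_params <- function(seed = 1L) {
  withr::local_seed(seed)
  augment_params(
    translation = runif(2, -30, 30),
    rotation = runif(3, -30, 30),
    magnification = runif(1, 0.7, 1.3)
  )
}

rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])), c(0, sin(r[1]), cos(r[1])))
  Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0), c(-sin(r[2]), 0, cos(r[2])))
  Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Apply a geometric augmentation to a training sample
#'
#' A single affine transform -- magnification, then rotation about the volume
#' center (order Rz Ry Rx), then in-plane translation -- is composed in
#' physical mm space and the sample is resampled back onto its own grid. The
#' image channel is linearly interpolated (out-of-field fill -1); labels,
#' diameters and weights use nearest-neighbor (fills 0, 0 and 1). Diameter
#' values are multiplied by the magnification factor so that diameters
#' expressed in voxels stay consistent with the magnified geometry.
#'
#' @param sample A [training_sample()].
#' @param params An [augment_params()].
#' @return A [training_sample()] on the same grid.
#' @export
augment <- function(sample, params) {
  stopifnot(inherits(sample, "training_sample"), inherits(params, "augment_params"))
  grid <- sample$grid
  ctr <- grid$origin + (grid$shape - 1) / 2 * grid$spacing
  R <- rotation_matrix(params$rotation)
  m <- params$magnification
  t3 <- c(params$translation, 0)
  Rinv <- t(R) # rotation matrices are orthogonal
  world_inv <- function(x) {
    y <- sweep(x, 2L, ctr + t3, "-")
    y <- y %*% t(Rinv) / m
    sweep(y, 2L, ctr, "+")
  }
  img <- resample_world(sample$image, grid, world_inv, "linear", fill = -1)
  lab <- resample_world(sample$labels3, grid, world_inv, "nearest", fill = 0)
  dvx <- resample_world(sample$diam_vox, grid, world_inv, "nearest", fill = 0) * m
  wts <- resample_world(sample$weights, grid, world_inv, "nearest", fill = 1)
  training_sample(pmin(pmax(img, -1), 1), array(as.integer(lab), grid$shape),
                  dvx, wts, grid)
}
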