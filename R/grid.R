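#' Voxel grid geometry
#'
#' A `volume_grid` fixes the geometry shared by all volumetric containers:
#' voxel counts per axis, voxel spacing in mm (anisotropic spacing is the norm
#' for thick-slice abdominal CT, e.g. 0.75 x 0.75 x 3.72 mm), and the world
#' position of the *center* of voxel (0,0,0). World coordinates follow
#' `world = origin + index * spacing` with 0-based indices; all geometry
#' (distances, augmentation) is computed in world mm so that anisotropy is
#' respected.
#'
#' @param shape Integer vector of length 3: voxels along x, y, z.
#' @param spacing Numeric length 3, mm per voxel (all > 0).
#' @param origin Numeric length 3, world mm of the center of the first voxel.
#' @return An object of class `volume_grid`.
#' @examples
#' volume_grid(c(512, 512, 128), spacing = c(0.75, 0.75, 3.72))
#' @export
volume_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(shape < 1L)) abort("`shape` must be 3 integers >= 1.")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive numbers (mm/voxel).")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) abort("`origin` must be 3 finite numbers.")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol
}

#' World coordinates of all voxel centers
#'
#' @param grid A [volume_grid()].
#' @return A `prod(shape) x 3` matrix of world mm, in R array (column-major,
#'   x-fastest) order.
#' @export
voxel_centers <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  s <- grid$shape
  xs <- grid$origin[1] + (seq_len(s[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(s[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(s[3]) - 1) * grid$spacing[3]
  cbind(
    rep(xs, times = s[2] * s[3]),
    rep(rep(ys, each = s[1]), times = s[3]),
    rep(zs, each = s[1] * s[2])
  )
}

# world mm -> continuous 0-based voxel index
world_to_index <- function(grid, xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  sweep(sweep(xyz, 2L, grid$origin, "-"), 2L, grid$spacing, "/")
}

index_to_world <- function(grid, idx) {
  idx <- matrix(idx, ncol = 3L)
  sweep(sweep(idx, 2L, grid$spacing, "*"), 2L, grid$origin, "+")
}

#' Volumetric label container
#'
#' Holds one integer gut label per voxel, 0 = background, under either the
#' 13-part (`"parts13"`) or the reduced 3-part (`"parts3"`) scheme.
#'
#' @param values Integer array matching `grid$shape`.
#' @param grid A [volume_grid()].
#' @param scheme `"parts13"` or `"parts3"`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(values, grid, scheme = c("parts13", "parts3")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(grid, "volume_grid"))
  if (!identical(dim(values), NULL) && !identical(as.integer(dim(values)), grid$shape)) {
    abort("`values` dimensions must match `grid$shape`.")
  }
  v <- as.integer(values)
  dim(v) <- grid$shape
  top <- if (scheme == "parts13") 13L else 3L
  if (anyNA(v) || min(v) < 0L || max(v) > top) {
    abort(sprintf("Label codes must be in 0..%d for scheme %s.", top, scheme))
  }
  structure(list(values = v, grid = grid, scheme = scheme), class = "label_volume")
}

#' Reduce a 13-part label volume to the 3-part scheme
#' @param lab A [label_volume()].
#' @return A `label_volume` tagged `"parts3"`.
#' @export
reduce_label_volume <- function(lab) {
  stopifnot(inherits(lab, "label_volume"))
  if (lab$scheme == "parts3") return(lab)
  label_volume(reduce_label(lab$values), lab$grid, scheme = "parts3")
}

#' Bowel diameter parametric map
#'
#' Holds one bowel-diameter value per voxel: a parametric image of bowel
#' caliber. Units are tagged (`"mm"` on reconstruction; `"voxels"` after
#' [diameter_to_voxels()]). A *masked* map is 0 outside the reconstructed
#' bowel; an unmasked (dense) map assigns the nearest segment's diameter
#' everywhere.
#'
#' @param values Numeric array matching `grid$shape`, all >= 0.
#' @param grid A [volume_grid()].
#' @param units `"mm"` or `"voxels"`.
#' @param masked Logical: is the map zero outside the bowel?
#' @return An object of class `diameter_map`.
#' @export
diameter_map <- function(values, grid, units = c("mm", "voxels"), masked = TRUE) {
  units <- match.arg(units)
  stopifnot(inherits(grid, "volume_grid"))
  v <- as.numeric(values)
  dim(v) <- grid$shape
  if (anyNA(v) || min(v) < 0) abort("Diameter values must be >= 0.")
  structure(list(values = v, grid = grid, units = units, masked = isTRUE(masked)),
            class = "diameter_map")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s, scheme %s, %d foreground voxel(s)\n",
              paste(x$grid$shape, collapse = "x"), x$scheme, sum(x$values != 0L)))
  invisible(x)
}

#' @export
print.diameter_map <- function(x, ...) {
  cat(sprintf("<diameter_map> %s, units %s, %s, %d non-zero voxel(s)\n",
              paste(x$grid$shape, collapse = "x"), x$units,
              if (x$masked) "masked" else "dense", sum(x$values > 0)))
  invisible(x)
}
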