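#' Read and write volumes as NIfTI
#'
#' Volumes are exchanged as NIfTI with an axis-aligned affine (positive
#' scaling plus translation), matching axial CT with the package's
#' world-coordinate convention `world = origin + index * spacing`. Label
#' volumes are written as unsigned 8-bit, diameter maps and CT as 32-bit
#' float (use `datatype = "double"` for lossless round trips).
#'
#' @param x An array, [label_volume()], [diameter_map()], or a list with
#'   `values` and `grid`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param grid A [volume_grid()] (required when `x` is a bare array).
#' @param datatype NIfTI datatype: `"uint8"`, `"float"`, or `"double"`;
#'   chosen automatically by container type when `NULL`.
#' @return `write_volume()` returns `path` invisibly. `read_volume()` returns
#'   a list with `values` (array) and `grid` (a [volume_grid()]).
#' @export
write_volume <- function(x, path, grid = NULL, datatype = NULL) {
  if (inherits(x, "label_volume")) {
    values <- x$values; grid <- x$grid
    datatype <- datatype %||% "uint8"
  } else if (inherits(x, "diameter_map")) {
    values <- x$values; grid <- x$grid
    datatype <- datatype %||% "float"
  } else if (is.list(x) && !is.null(x$values) && !is.null(x$grid)) {
    values <- x$values; grid <- x$grid
    datatype <- datatype %||% "float"
  } else {
    values <- x
    if (is.null(grid)) abort("`grid` is required when writing a bare array.")
    datatype <- datatype %||% "float"
  }
  stopifnot(inherits(grid, "volume_grid"))
  if (!datatype %in% c("uint8", "float", "double")) abort("Unsupported datatype.")
  hdr <- list(pixdim = c(-1, grid$spacing, 0, 0, 0, 0))
  img <- RNifti::asNifti(array(as.numeric(values), grid$shape), reference = hdr)
  aff <- rbind(cbind(diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(paste0("No such volume file: ", path))
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  lin <- aff[1:3, 1:3]
  if (max(abs(lin - diag(diag(lin)))) > 1e-6 * max(abs(diag(lin)))) {
    abort("Unsupported orientation: the affine must be axis-aligned scaling plus translation (field srow/qform).")
  }
  spacing <- diag(lin)
  if (any(spacing <= 0)) {
    abort("Unsupported orientation: negative or zero scaling in the affine (field pixdim).")
  }
  values <- as.array(img)
  attributes(values) <- list(dim = dim(values))
  grid <- volume_grid(dim(values), spacing = spacing, origin = aff[1:3, 4L])
  list(values = values, grid = grid)
}

#' Write and read a phantom bundle
#'
#' A phantom on disk is a directory holding `ct.nii.gz`, `labels.nii.gz`,
#' `diam.nii.gz`, `tubes.json` (exact centerlines and diameter profiles) and
#' `meta.yaml` (seed and generation parameters).
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Directory (created if needed).
#' @return `write_phantom()` returns `dir` invisibly; `read_phantom()`
#'   returns a `phantom_volume`.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$ct, file.path(dir, "ct.nii.gz"), grid = phantom$grid,
               datatype = "double")
  write_volume(phantom$truth_labels, file.path(dir, "labels.nii.gz"))
  write_volume(phantom$truth_diameters, file.path(dir, "diam.nii.gz"),
               datatype = "double")
  tubes <- lapply(phantom$tubes, function(tb) {
    list(control_points = apply(tb$control_points, 1L, function(r) as.list(r),
                                simplify = FALSE),
         diameter_profile = tb$diameter_profile,
         label = tb$label, lumen_hu = tb$lumen_hu, wall_hu = tb$wall_hu)
  })
  jsonlite::write_json(tubes, file.path(dir, "tubes.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(c(list(scan_id = phantom$scan_id), phantom$params),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  ct <- read_volume(file.path(dir, "ct.nii.gz"))
  lab <- read_volume(file.path(dir, "labels.nii.gz"))
  dm <- read_volume(file.path(dir, "diam.nii.gz"))
  tubes_raw <- jsonlite::read_json(file.path(dir, "tubes.json"),
                                   simplifyVector = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  tubes <- lapply(tubes_raw, function(tb) {
    P <- do.call(rbind, lapply(tb$control_points, function(p) unlist(p)))
    list(control_points = unname(P),
         diameter_profile = unlist(tb$diameter_profile),
         label = as.integer(tb$label), lumen_hu = tb$lumen_hu,
         wall_hu = tb$wall_hu)
  })
  structure(list(
    ct = ct$values, grid = ct$grid,
    truth_labels = label_volume(lab$values, lab$grid, scheme = "parts13"),
    truth_diameters = diameter_map(dm$values, dm$grid, units = "mm",
                                   masked = TRUE),
    tubes = tubes, scan_id = meta$scan_id,
    params = meta[setdiff(names(meta), "scan_id")]
  ), class = "phantom_volume")
}

#' Read a run configuration file
#'
#' YAML configuration for the command-line pipeline. Recognized top-level
#' keys: `seed`, `phantom`, `noise`, `preprocessing`, `model`, `training`,
#' `comparison`. Unknown keys are rejected so that typos fail loudly rather
#' than silently falling back to defaults.
#'
#' @param path YAML file path.
#' @return A named list of configuration sections.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such config file: ", path))
  cfg <- yaml::read_yaml(path)
  allowed <- c("seed", "phantom", "noise", "preprocessing", "model",
               "training", "comparison")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg
}
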