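#' Construct a gaze-based scan annotation
#'
#' A scan annotation is the primitive produced by eye-tracked ("visual")
#' annotation of a CT scan: an ordered series of segments, each a run of gaze
#' points tracing the bowel centerline. Every gaze point carries a 3-D position
#' in scanner/world millimetres and an annotator-set approximate bowel
#' diameter; every segment carries one of the 13 gastrointestinal part labels
#' (see [gut_parts()]). Annotation of a scan is typically repeated twice so
#' that repeatability can be quantified downstream.
#'
#' @param points A data frame with one row per gaze point, in recording order,
#'   with columns `segment` (integer segment index), `label` (13-part code or
#'   part name), `x`, `y`, `z` (mm, world coordinates) and `diameter` (mm).
#' @param scan_id Scan identifier string.
#' @param repetition Annotation repetition, 1 or 2.
#' @return A tibble of class `scan_annotation` with columns `scan_id`,
#'   `repetition`, `segment`, `label`, `x`, `y`, `z`, `diameter`.
#' @examples
#' pts <- tibble::tibble(
#'   segment = c(1, 1, 2), label = c(4, 4, 5),
#'   x = c(0, 10, 40), y = c(0, 0, 5), z = c(0, 0, 0),
#'   diameter = c(20, 22, 18)
#' )
#' ann <- scan_annotation(pts, scan_id = "demo", repetition = 1)
#' segment_length(ann)
#' @export
scan_annotation <- function(points, scan_id = "scan", repetition = 1L) {
  points <- tibble::as_tibble(points)
  needed <- c("segment", "label", "x", "y", "z", "diameter")
  missing_cols <- setdiff(needed, names(points))
  if (length(missing_cols)) {
    abort(paste0("`points` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(points) == 0L) abort("An annotation must contain at least one gaze point.")
  if (is.character(points$label)) points$label <- part_name_to_code(points$label)
  points$label <- as.integer(points$label)
  points$segment <- as.integer(points$segment)
  if (!all(points$label %in% 1:13)) abort("Segment labels must be 13-part codes in 1..13.")
  pos <- as.matrix(points[, c("x", "y", "z")])
  if (!all(is.finite(pos))) abort("Gaze point positions must be finite.")
  if (!all(is.finite(points$diameter)) || any(points$diameter <= 0)) {
    abort("Gaze point diameters must be finite and > 0.")
  }
  lab_per_seg <- tapply(points$label, points$segment, function(l) length(unique(l)))
  if (any(lab_per_seg != 1L)) abort("Each segment must carry a single label.")
  repetition <- as.integer(repetition)
  if (!repetition %in% c(1L, 2L)) abort("`repetition` must be 1 or 2.")
  out <- tibble::tibble(
    scan_id = as.character(scan_id), repetition = repetition,
    segment = points$segment, label = points$label,
    x = as.numeric(points$x), y = as.numeric(points$y), z = as.numeric(points$z),
    diameter = as.numeric(points$diameter)
  )
  class(out) <- c("scan_annotation", class(out))
  out
}

#' @export
print.scan_annotation <- function(x, ...) {
  cat(sprintf(
    "<scan_annotation> scan %s, repetition %d: %d segment(s), %d gaze point(s)\n",
    x$scan_id[1], x$repetition[1], length(unique(x$segment)), nrow(x)
  ))
  NextMethod()
}

#' Per-segment polyline lengths of an annotation
#'
#' The length of a visual segment is the sum of Euclidean distances between
#' sequential gaze points; a single-point segment has length 0.
#'
#' @param annotation A [scan_annotation()], or any data frame with `x`, `y`,
#'   `z` columns (and optionally `segment`; a single segment is assumed
#'   otherwise).
#' @return A tibble with one row per segment: `segment`, `label` (if present),
#'   `n_points`, `length_mm`.
#' @export
segment_length <- function(annotation) {
  df <- tibble::as_tibble(annotation)
  if (nrow(df) == 0L) abort("Cannot compute the length of an empty segment.")
  if (!all(c("x", "y", "z") %in% names(df))) abort("Need `x`, `y`, `z` columns.")
  if (!"segment" %in% names(df)) df$segment <- 1L
  has_label <- "label" %in% names(df)
  df$..step <- polyline_steps(df)
  keys <- intersect(c("scan_id", "repetition", "segment"), names(df))
  out <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(keys))),
    label = if (has_label) .data$label[1L] else NA_integer_,
    n_points = dplyr::n(),
    length_mm = sum(.data$..step),
    .groups = "drop"
  )
  cols <- c(keys, if (has_label) "label", "n_points", "length_mm")
  out[, cols]
}

# distance from the previous gaze point within the same segment (0 at starts)
polyline_steps <- function(df) {
  n <- nrow(df)
  if (n == 1L) return(0)
  d <- sqrt(diff(df$x)^2 + diff(df$y)^2 + diff(df$z)^2)
  keys <- intersect(c("scan_id", "repetition", "segment"), names(df))
  key <- do.call(paste, c(df[keys], sep = "\r"))
  same <- key[-1L] == key[-n]
  c(0, d * same)
}

#' Summarise a scan annotation
#'
#' Per-scan accounting of the visual annotation effort: number of segments and
#' gaze points, total traced bowel length, and gaze recording time. Each gaze
#' point represents one averaging interval of the eye tracker (0.75 s of 60 Hz
#' samples by default), so recording time is `n_gaze_points * dwell`. The
#' recording time counts retained gaze points only; time spent deducing the
#' bowel course, calibrating, or redoing segments is not represented.
#'
#' @param annotation A [scan_annotation()] (or a row-bound collection of them;
#'   summaries are then per scan/repetition).
#' @param dwell Seconds of eye-tracker recording represented by one gaze
#'   point (default 0.75).
#' @return A tibble with columns `scan_id`, `repetition`, `n_segments`,
#'   `n_gaze_points`, `total_length_mm`, `recording_time_s`.
#' @export
annotation_summary <- function(annotation, dwell = 0.75) {
  df <- tibble::as_tibble(annotation)
  if (!"scan_id" %in% names(df)) df$scan_id <- "scan"
  if (!"repetition" %in% names(df)) df$repetition <- 1L
  df$..step <- polyline_steps(df)
  dplyr::summarise(
    dplyr::group_by(df, .data$scan_id, .data$repetition),
    n_segments = dplyr::n_distinct(.data$segment),
    n_gaze_points = dplyr::n(),
    total_length_mm = sum(.data$..step),
    recording_time_s = dplyr::n() * dwell,
    .groups = "drop"
  )
}

#' Read and write gaze annotations as JSON
#'
#' One JSON object per scan-repetition:
#' `{scan_id, repetition, segments: [{label, points: [{xyz_mm: [x,y,z],
#' diameter_mm}]}]}`.
#'
#' @param annotation A [scan_annotation()].
#' @param path File path.
#' @return `write_annotation()` returns `path` invisibly; `read_annotation()`
#'   returns a [scan_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "scan_annotation"))
  segs <- split(annotation, annotation$segment)
  segs <- segs[order(as.integer(names(segs)))]
  obj <- list(
    scan_id = annotation$scan_id[1L],
    repetition = annotation$repetition[1L],
    segments = lapply(segs, function(s) {
      list(
        label = s$label[1L],
        points = lapply(seq_len(nrow(s)), function(i) {
          list(xyz_mm = c(s$x[i], s$y[i], s$z[i]), diameter_mm = s$diameter[i])
        })
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  pts <- purrr::imap_dfr(obj$segments, function(s, i) {
    m <- do.call(rbind, lapply(s$points, function(p) unlist(p$xyz_mm)))
    tibble::tibble(
      segment = as.integer(i), label = as.integer(s$label),
      x = m[, 1], y = m[, 2], z = m[, 3],
      diameter = vapply(s$points, function(p) as.numeric(p$diameter_mm), 0)
    )
  })
  scan_annotation(pts, scan_id = obj$scan_id, repetition = obj$repetition)
}
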