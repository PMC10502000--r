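#' Gastrointestinal label schemes
#'
#' The annotation scheme distinguishes 13 parts of the gastrointestinal tract,
#' coded 1--13 with 0 reserved for background. For training and agreement
#' analysis the 13 parts collapse to a 3-part scheme chosen to match diameter
#' thresholds for obstruction (roughly 3 cm for small bowel, 6 cm for large
#' bowel) rather than embryologic boundaries: foregut runs esophagus through
#' duodenum, midgut is jejunum and ileum, hindgut runs cecum through anus.
#'
#' @return A tibble with one row per 13-part code (plus background): `code13`,
#'   `part` (name), `code3`, `group` (foregut/midgut/hindgut/background).
#' @examples
#' gut_parts()
#' @export
gut_parts <- function() {
  parts <- c(
    "esophagus", "stomach", "duodenum", "jejunum", "ileum", "cecum",
    "appendix", "ascending colon", "transverse colon", "descending colon",
    "sigmoid colon", "rectum", "anus"
  )
  code3 <- c(1L, 1L, 1L, 2L, 2L, rep(3L, 8L))
  tibble::tibble(
    code13 = c(0L, seq_along(parts)),
    part = c("background", parts),
    code3 = c(0L, code3),
    group = c("background", c("foregut", "midgut", "hindgut")[code3])
  )
}

#' Reduce 13-part gut labels to the 3-part scheme
#'
#' Maps esophagus/stomach/duodenum to foregut (1), jejunum/ileum to midgut (2),
#' cecum through anus to hindgut (3); background (0) is preserved.
#'
#' @param code13 Integer vector (or array) of 13-part codes in 0..13.
#' @return Integer codes in 0..3, same shape as the input.
#' @examples
#' reduce_label(c(0, 3, 4, 13))
#' @export
reduce_label <- function(code13) {
  x <- as.integer(code13)
  bad <- !is.na(x) & (x < 0L | x > 13L)
  if (any(bad) || anyNA(x)) {
    abort("`code13` must contain codes in 0..13 with no missing values.")
  }
  map <- c(0L, 1L, 1L, 1L, 2L, 2L, rep(3L, 8L)) # index = code13 + 1
  out <- map[x + 1L]
  if (is.array(code13)) dim(out) <- dim(code13)
  out
}

part_name_to_code <- function(part) {
  tab <- gut_parts()
  idx <- match(part, tab$part)
  if (anyNA(idx)) {
    abort(paste0("Unknown gut part name(s): ",
                 paste(unique(part[is.na(idx)]), collapse = ", ")))
  }
  tab$code13[idx]
}
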