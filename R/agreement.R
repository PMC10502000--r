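#' Dice overlap coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Undefined (returned as `NA`) when both
#' masks are empty; comparisons exclude such cases.
#'
#' @param a,b Logical arrays of identical dimensions, or [label_volume()]s on
#'   identical grids (any non-background voxel counts as foreground).
#' @return A number in \[0, 1\], or `NA` when both masks are empty.
#' @examples
#' m <- array(FALSE, c(4, 4, 1)); m[1:2, 1, 1] <- TRUE
#' dice(m, m)
#' @export
dice <- function(a, b) {
  if (inherits(a, "label_volume") && inherits(b, "label_volume")) {
    if (!grids_equal(a$grid, b$grid)) abort("Masks live on different grids.")
    a <- a$values != 0L
    b <- b$values != 0L
  }
  if (!identical(dim(a), dim(b))) abort("Masks live on different grids.")
  a <- as.logical(a); b <- as.logical(b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(NA_real_)
  2 * sum(a & b) / (na + nb)
}

#' Per-part Dice scores between two label volumes
#'
#' Computes the Dice score for the whole foreground (`"all"`) and for each
#' label code present in the scheme. A part empty in both volumes yields `NA`
#' (excluded downstream); a part empty in exactly one yields 0.
#'
#' @param a,b [label_volume()]s on the same grid and scheme.
#' @return A tibble: `part` (label code as character, `"all"` first), `dice`,
#'   `n_a`, `n_b` (foreground voxel counts).
#' @export
dice_by_part <- function(a, b) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  if (!grids_equal(a$grid, b$grid)) abort("Label volumes live on different grids.")
  if (!identical(a$scheme, b$scheme)) abort("Label volumes use different schemes.")
  codes <- seq_len(if (a$scheme == "parts3") 3L else 13L)
  rows <- purrr::map_dfr(c("all", as.character(codes)), function(pt) {
    if (pt == "all") {
      ma <- a$values != 0L; mb <- b$values != 0L
    } else {
      code <- as.integer(pt)
      ma <- a$values == code; mb <- b$values == code
    }
    tibble::tibble(part = pt, dice = dice(ma, mb), n_a = sum(ma), n_b = sum(mb))
  })
  rows
}

#' Two-way agreement intraclass correlation, ICC(A,1)
#'
#' Single-rater, absolute-agreement ICC from a two-way random-effects model
#' (McGraw & Wong's ICC(A,1)): `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC -
#' MSE))`, with mean squares from the two-way subject-by-rater ANOVA and the
#' 95% confidence interval from the F-based approximation. Absolute agreement
#' (rather than consistency) penalizes systematic offsets between raters,
#' which is the relevant notion when comparing repeated diameter
#' measurements.
#'
#' @param data A data frame whose columns are raters/methods (one row per
#'   subject/site), or a numeric `n x k` matrix. At least 3 subjects and 2
#'   raters, no missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `icc`, `ci_low`, `ci_high`, `n`, `k`,
#'   `degenerate` (TRUE when total variance is zero, in which case icc is
#'   defined as 1 with a degenerate CI).
#' @examples
#' d <- data.frame(a = c(1, 2, 3, 4), b = c(1.1, 2.2, 2.9, 4.3))
#' icc_two_way_agreement(d)
#' @export
icc_two_way_agreement <- function(data, conf_level = 0.95) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) abort("Need at least 3 subjects.")
  if (k < 2L) abort("Need at least 2 raters.")
  if (anyNA(x)) abort("Missing cells are not supported.")
  grand <- mean(x)
  if (sum((x - grand)^2) == 0) {
    return(tibble::tibble(icc = 1, ci_low = 1, ci_high = 1, n = n, k = k,
                          degenerate = TRUE))
  }
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  if (!is.finite(lower) || !is.finite(upper)) {
    # perfect agreement (mse == 0): the F-based interval collapses
    lower <- icc
    upper <- icc
  }
  tibble::tibble(icc = icc, ci_low = lower, ci_high = upper, n = n, k = k,
                 degenerate = FALSE)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' For paired measurements the differences `d = a - b` give the bias
#' (`mean(d)`) and the 95% limits of agreement half-width (`1.96 * sd(d)`,
#' sample standard deviation).
#'
#' @param data A data frame containing the two measurement columns.
#' @param a,b Column names (tidy-eval) of the paired measurements.
#' @return A one-row tibble: `bias`, `loa_halfwidth`, `loa_lower`,
#'   `loa_upper`, `n`.
#' @examples
#' d <- data.frame(rep1 = c(10, 20, 30), rep2 = c(11, 19, 33))
#' limits_of_agreement(d, rep1, rep2)
#' @export
limits_of_agreement <- function(data, a, b) {
  av <- dplyr::pull(data, {{ a }})
  bv <- dplyr::pull(data, {{ b }})
  if (length(av) < 2L) abort("Need at least 2 pairs.")
  d <- av - bv
  bias <- mean(d)
  hw <- 1.96 * sd(d)
  tibble::tibble(bias = bias, loa_halfwidth = hw,
                 loa_lower = bias - hw, loa_upper = bias + hw, n = length(d))
}

#' Sample a diameter map at world locations
#'
#' Reads the diameter value at the voxel nearest to each location. On a
#' masked map, a zero at the nearest voxel triggers a search for the nearest
#' non-zero voxel within `search_radius` mm (this is how caliper sites placed
#' at the bowel wall or just outside the reconstructed lumen are matched to
#' the annotated diameter).
#'
#' @param map A [diameter_map()].
#' @param sites A data frame with world-mm columns `x`, `y`, `z`.
#' @param search_radius Search radius in mm for the nearest non-zero voxel on
#'   masked maps (default 5).
#' @return `sites` with an added `diameter` column (in `map$units`).
#' @export
sample_diameter_at <- function(map, sites, search_radius = 5) {
  stopifnot(inherits(map, "diameter_map"))
  sites <- tibble::as_tibble(sites)
  loc <- as.matrix(sites[, c("x", "y", "z")])
  grid <- map$grid
  idx <- world_to_index(grid, loc)
  ni <- floor(idx + 0.5)
  oob <- ni[, 1L] < 0 | ni[, 1L] > grid$shape[1L] - 1 |
    ni[, 2L] < 0 | ni[, 2L] > grid$shape[2L] - 1 |
    ni[, 3L] < 0 | ni[, 3L] > grid$shape[3L] - 1
  if (any(oob)) abort("Location(s) outside the grid bounds.")
  vals <- map$values[ni + 1L]
  need_search <- map$masked & vals == 0
  if (any(need_search)) {
    nz <- which(map$values > 0)
    if (length(nz) == 0L) abort("No non-zero diameter voxel within the search radius.")
    co <- arrayInd(nz, grid$shape) - 1L
    w <- index_to_world(grid, co)
    for (i in which(need_search)) {
      d2 <- (w[, 1L] - loc[i, 1L])^2 + (w[, 2L] - loc[i, 2L])^2 +
        (w[, 3L] - loc[i, 3L])^2
      j <- which.min(d2)
      if (sqrt(d2[j]) > search_radius) {
        abort(sprintf("No non-zero diameter voxel within %.1f mm of site %d.",
                      search_radius, i))
      }
      vals[i] <- map$values[nz[j]]
    }
  }
  sites$diameter <- vals
  sites
}

#' Pair caliper measurements with a diameter map
#'
#' Looks up the annotated/predicted diameter at each caliper site and pairs
#' it with the manual value: the mean of short and long axis by default (the
#' caliper pair straddles the bowel cross-section, so their mean is the
#' natural single-number caliber), or short/long only.
#'
#' @param calipers A tibble from [simulate_calipers()] (or any table with
#'   `x`, `y`, `z`, `short_axis`, `long_axis`).
#' @param map A [diameter_map()] in mm.
#' @param value `"mean"`, `"short"` or `"long"`.
#' @param search_radius Passed to [sample_diameter_at()].
#' @return `calipers` with `manual` and `mapped` columns (mm).
#' @export
pair_calipers_with_map <- function(calipers, map, value = c("mean", "short", "long"),
                                   search_radius = 5) {
  value <- match.arg(value)
  if (map$units != "mm") abort("`map` must be in mm to compare with calipers.")
  out <- sample_diameter_at(map, calipers, search_radius)
  out$manual <- switch(value,
    mean = (out$short_axis + out$long_axis) / 2,
    short = out$short_axis,
    long = out$long_axis
  )
  out$mapped <- out$diameter
  out$diameter <- NULL
  out
}

#' Compare two annotation or prediction sources
#'
#' The full agreement pipeline between two sources (two repetitions of visual
#' annotation, annotation vs network prediction, ...): per-part and whole-gut
#' Dice across scans, plus ICC(A,1) and Bland-Altman limits of agreement over
#' matched diameter pairs sampled at shared sites. A (scan, part) empty in
#' both sources is excluded from that part's Dice (its `n` is decremented);
#' empty in exactly one counts as Dice 0. With `exclusion = "either"` a part
#' empty in either source is excluded instead.
#'
#' @param a,b Named lists of scans; each scan is a list with `labels` (a
#'   [label_volume()]) and `diameters` (a [diameter_map()], mm). Names are
#'   scan ids and must match between `a` and `b`.
#' @param sites Optional tibble of diameter sampling sites with columns
#'   `scan_id`, `x`, `y`, `z`; when given, diameter agreement (ICC, LOA) is
#'   computed over pairs sampled from both sources at these sites.
#' @param parts `"parts3"` (default) or `"parts13"`; 13-part volumes are
#'   reduced when `"parts3"`.
#' @param exclusion `"both"` (default) or `"either"`.
#' @param search_radius Passed to [sample_diameter_at()].
#' @return An object of class `agreement_report`: list with `dice` (tibble:
#'   part, mean, sd, n), `per_scan_dice`, `icc`, `loa`, `pairs`.
#' @export
compare_sources <- function(a, b, sites = NULL, parts = c("parts3", "parts13"),
                            exclusion = c("both", "either"), search_radius = 5) {
  parts <- match.arg(parts)
  exclusion <- match.arg(exclusion)
  if (length(a) == 0L || length(a) != length(b)) {
    abort("`a` and `b` must be non-empty lists of equal length.")
  }
  ids <- names(a) %||% as.character(seq_along(a))
  ids_b <- names(b) %||% as.character(seq_along(b))
  if (!identical(sort(ids), sort(ids_b))) abort("Scan ids of `a` and `b` differ.")
  b <- b[ids]

  get_lab <- function(scan) {
    lab <- scan$labels
    if (parts == "parts3") lab <- reduce_label_volume(lab) else {
      if (lab$scheme != "parts13") abort("13-part comparison needs 13-part labels.")
    }
    lab
  }
  per_scan <- purrr::map_dfr(ids, function(id) {
    d <- dice_by_part(get_lab(a[[id]]), get_lab(b[[id]]))
    d$scan_id <- id
    d
  })
  # exclusion rules
  if (exclusion == "both") {
    per_scan <- per_scan[!(per_scan$n_a == 0L & per_scan$n_b == 0L), ]
  } else {
    per_scan <- per_scan[per_scan$n_a > 0L & per_scan$n_b > 0L, ]
  }
  per_scan$dice[is.na(per_scan$dice)] <- 0 # empty-in-one after "both" rule
  dice_tab <- dplyr::summarise(
    dplyr::group_by(per_scan, .data$part),
    mean = mean(.data$dice), sd = sd(.data$dice), n = dplyr::n(),
    .groups = "drop"
  )

  pairs <- NULL; icc_tab <- NULL; loa_tab <- NULL
  if (!is.null(sites)) {
    sites <- tibble::as_tibble(sites)
    if (!"scan_id" %in% names(sites)) sites$scan_id <- ids[1L]
    pairs <- purrr::map_dfr(ids, function(id) {
      st <- sites[sites$scan_id == id, , drop = FALSE]
      if (nrow(st) == 0L) return(NULL)
      da <- sample_diameter_at(a[[id]]$diameters, st, search_radius)$diameter
      db <- sample_diameter_at(b[[id]]$diameters, st, search_radius)$diameter
      tibble::tibble(scan_id = id, x = st$x, y = st$y, z = st$z,
                     diameter_a = da, diameter_b = db)
    })
    if (!is.null(pairs) && nrow(pairs) >= 3L) {
      icc_tab <- icc_two_way_agreement(pairs[, c("diameter_a", "diameter_b")])
      loa_tab <- limits_of_agreement(pairs, .data$diameter_a, .data$diameter_b)
    }
  }
  structure(list(dice = dice_tab, per_scan_dice = per_scan, icc = icc_tab,
                 loa = loa_tab, pairs = pairs, parts = parts,
                 n_scans = length(ids)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d scan(s), %s scheme\n", x$n_scans, x$parts))
  all_row <- x$dice[x$dice$part == "all", ]
  if (nrow(all_row)) {
    cat(sprintf("  Dice (all parts): %.3f +/- %.3f (n = %d)\n",
                all_row$mean, all_row$sd, all_row$n))
  }
  if (!is.null(x$icc)) {
    cat(sprintf("  ICC(A,1): %.3f [%.3f-%.3f], n = %d pairs\n",
                x$icc$icc, x$icc$ci_low, x$icc$ci_high, x$icc$n))
  }
  if (!is.null(x$loa)) {
    cat(sprintf("  Bias +/- 95%% LOA: %.2f +/- %.2f mm\n",
                x$loa$bias, x$loa$loa_halfwidth))
  }
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) {
  out <- dplyr::mutate(x$dice, metric = "dice", .before = 1L)
  out <- dplyr::rename(out, value = "mean")
  rows <- list(out[, c("metric", "part", "value", "sd", "n")])
  if (!is.null(x$icc)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      metric = "icc", part = "all", value = x$icc$icc, sd = NA_real_,
      n = x$icc$n)
  }
  if (!is.null(x$loa)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      metric = c("bias", "loa_halfwidth"), part = "all",
      value = c(x$loa$bias, x$loa$loa_halfwidth), sd = NA_real_, n = x$loa$n)
  }
  dplyr::bind_rows(rows)
}

#' @export
glance.agreement_report <- function(x, ...) {
  all_row <- x$dice[x$dice$part == "all", ]
  tibble::tibble(
    n_scans = x$n_scans,
    dice_all = if (nrow(all_row)) all_row$mean else NA_real_,
    icc = if (!is.null(x$icc)) x$icc$icc else NA_real_,
    bias = if (!is.null(x$loa)) x$loa$bias else NA_real_,
    loa_halfwidth = if (!is.null(x$loa)) x$loa$loa_halfwidth else NA_real_
  )
}

#' Bland-Altman plot of an agreement report
#'
#' @param object An [compare_sources()] report with diameter pairs.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.agreement_report <- function(object, ...) {
  if (is.null(object$pairs)) abort("Report holds no diameter pairs to plot.")
  p <- object$pairs
  p$mean_d <- (p$diameter_a + p$diameter_b) / 2
  p$diff_d <- p$diameter_a - p$diameter_b
  loa <- object$loa
  gg <- ggplot2::ggplot(p, ggplot2::aes(x = .data$mean_d, y = .data$diff_d)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "Mean diameter (mm)", y = "Difference (mm)",
                  title = "Bland-Altman agreement of diameters")
  if (!is.null(loa)) {
    gg <- gg +
      ggplot2::geom_hline(yintercept = loa$bias, linetype = 1) +
      ggplot2::geom_hline(yintercept = c(loa$loa_lower, loa$loa_upper),
                          linetype = 2)
  }
  gg
}
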