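# Internal resampling machinery.
#
# Conventions: continuous voxel indices are 0-based; a voxel's center is at
# integer index i; world = origin + i * spacing. Nearest-neighbor uses
# floor(i + 0.5) (ties round up), which is deterministic for the exact
# half-integer indices that arise with integer decimation factors.

# Gather values at continuous 0-based indices (n x 3), nearest neighbor.
gather_nearest <- function(arr, idx, fill = 0) {
  shp <- dim(arr)
  ni <- floor(idx + 0.5) + 1 # 1-based
  valid <- ni[, 1L] >= 1 & ni[, 1L] <= shp[1L] &
    ni[, 2L] >= 1 & ni[, 2L] <= shp[2L] &
    ni[, 3L] >= 1 & ni[, 3L] <= shp[3L]
  out <- rep(fill, nrow(idx))
  if (any(valid)) {
    out[valid] <- arr[cbind(ni[valid, 1L], ni[valid, 2L], ni[valid, 3L])]
  }
  out
}

# Trilinear gather; corners outside the array contribute `fill`.
gather_linear <- function(arr, idx, fill = 0) {
  shp <- dim(arr)
  lo <- floor(idx)
  fr <- idx - lo
  out <- numeric(nrow(idx))
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    w <- (if (ox) fr[, 1L] else 1 - fr[, 1L]) *
      (if (oy) fr[, 2L] else 1 - fr[, 2L]) *
      (if (oz) fr[, 3L] else 1 - fr[, 3L])
    ci <- cbind(lo[, 1L] + ox + 1, lo[, 2L] + oy + 1, lo[, 3L] + oz + 1)
    valid <- ci[, 1L] >= 1 & ci[, 1L] <= shp[1L] &
      ci[, 2L] >= 1 & ci[, 2L] <= shp[2L] &
      ci[, 3L] >= 1 & ci[, 3L] <= shp[3L]
    vals <- rep(fill, nrow(idx))
    if (any(valid)) vals[valid] <- arr[ci[valid, , drop = FALSE]]
    out <- out + w * vals
  }
  out
}

# Resample `arr` (on `grid`) through an inverse world mapping: the output
# voxel at world position x takes the input value at world_inv(x).
resample_world <- function(arr, grid, world_inv, method = c("linear", "nearest"),
                           fill = 0) {
  method <- match.arg(method)
  xout <- voxel_centers(grid)
  xin <- world_inv(xout)
  idx <- world_to_index(grid, xin)
  out <- if (method == "nearest") gather_nearest(arr, idx, fill) else
    gather_linear(arr, idx, fill)
  dim(out) <- grid$shape
  out
}

# Separable center-aligned resize of one axis (first axis of `arr`).
resize_first_axis <- function(arr, new_n, method) {
  old_n <- dim(arr)[1L]
  if (new_n == old_n) return(arr)
  scale <- old_n / new_n
  ii <- (seq_len(new_n) - 0.5) * scale - 0.5 # 0-based continuous
  if (method == "nearest") {
    ni <- pmin(pmax(floor(ii + 0.5), 0), old_n - 1) + 1
    return(do_index_first(arr, ni))
  }
  lo <- pmin(pmax(floor(ii), 0), old_n - 1)
  hi <- pmin(lo + 1, old_n - 1)
  fr <- pmin(pmax(ii - lo, 0), 1)
  a_lo <- do_index_first(arr, lo + 1)
  a_hi <- do_index_first(arr, hi + 1)
  sweep_mul <- function(a, w) a * array(w, dim = dim(a))
  sweep_mul(a_lo, 1 - fr) + sweep_mul(a_hi, fr)
}

do_index_first <- function(arr, i) {
  d <- dim(arr)
  out <- if (length(d) == 3L) arr[i, , , drop = FALSE] else arr[i, , drop = FALSE]
  out
}

# Full separable resize: `methods` can differ per axis.
resize_array <- function(arr, new_shape, method = "linear") {
  d <- length(dim(arr))
  stopifnot(length(new_shape) == d)
  method <- rep(method, length.out = d)
  perm <- if (d == 3L) c(2L, 3L, 1L) else c(2L, 1L)
  for (ax in seq_len(d)) {
    arr <- resize_first_axis(arr, new_shape[1L], method[1L])
    arr <- aperm(arr, perm)
    new_shape <- new_shape[c(seq_len(d)[-1L], 1L)]
    method <- method[c(seq_len(d)[-1L], 1L)]
  }
  arr
}
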