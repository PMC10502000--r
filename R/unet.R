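#' U-net configuration
#'
#' Describes the dual-output U-net topology. Each *block* holds two
#' convolution layers with ReLU activations, batch normalization and dropout;
#' descending blocks end in 2x max pooling, ascending blocks start with 2x
#' nearest-neighbor upsampling and a skip concatenation with the equal-shape
#' descending block. With `n_levels` levels the network has `2 * n_levels`
#' blocks and its midpoint shape is `input_shape / 2^n_levels`. Channel count
#' starts at `base_channels` and is multiplied by `growth` per level. Two
#' heads leave the final full-resolution level: a 4-class softmax
#' segmentation (background/foregut/midgut/hindgut) and a softplus diameter
#' regression (softplus keeps predicted diameters non-negative with smooth
#' gradients).
#'
#' Reference-scale settings are `dims = 2, input_shape = c(256, 256),
#' base_channels = 8, n_levels = 7` (14 blocks, 2x2 midpoint) and `dims = 3,
#' input_shape = c(128, 128, 64), base_channels = 16, n_levels = 5` (10
#' blocks, 4x4x2 midpoint). [desk_unet_config()] is a small CPU-friendly
#' preset used throughout the tests.
#'
#' @param dims 2 or 3.
#' @param input_shape Spatial input shape (length `dims`); every axis must be
#'   divisible by `2^n_levels`.
#' @param base_channels Channels of the first level (default 8 for 2d, 16 for
#'   3d).
#' @param n_levels Number of levels (default 7 for 2d, 5 for 3d).
#' @param dropout Dropout rate inside every block.
#' @param growth Channel growth factor per level (default 2).
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(dims = 2, input_shape = if (dims == 2) c(256, 256) else c(128, 128, 64),
                        base_channels = if (dims == 2) 8 else 16,
                        n_levels = if (dims == 2) 7 else 5,
                        dropout = 0.1, growth = 2) {
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) abort("`dims` must be 2 or 3.")
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != dims) abort("`input_shape` must have length `dims`.")
  if (any(input_shape %% 2L^n_levels != 0L)) {
    abort(sprintf("Every input axis must be divisible by 2^n_levels = %d.", 2^n_levels))
  }
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1).")
  structure(list(dims = dims, input_shape = input_shape,
                 base_channels = as.integer(base_channels),
                 n_levels = as.integer(n_levels), dropout = dropout,
                 growth = growth), class = "unet_config")
}

#' @rdname unet_config
#' @export
desk_unet_config <- function(dims = 2, input_shape = if (dims == 2) c(64, 64) else c(16, 16, 8),
                             base_channels = 4, n_levels = 3, dropout = 0) {
  unet_config(dims = dims, input_shape = input_shape,
              base_channels = base_channels, n_levels = n_levels,
              dropout = dropout)
}

new_block <- function(d, in_ch, out_ch, dropout) {
  list(
    conv1 = layer_conv(d, in_ch, out_ch), relu1 = layer_relu(),
    conv2 = layer_conv(d, out_ch, out_ch), relu2 = layer_relu(),
    bn = layer_bn(out_ch), drop = layer_dropout(dropout)
  )
}

block_forward <- function(blk, x, sp, N, training) {
  x <- blk$conv1$fw(x, sp, N, training)
  x <- blk$relu1$fw(x, training)
  x <- blk$conv2$fw(x, sp, N, training)
  x <- blk$relu2$fw(x, training)
  x <- blk$bn$fw(x, training)
  blk$drop$fw(x, training)
}

block_backward <- function(blk, dy) {
  dy <- blk$drop$bw(dy)
  dy <- blk$bn$bw(dy)
  dy <- blk$relu2$bw(dy)
  dy <- blk$conv2$bw(dy)
  dy <- blk$relu1$bw(dy)
  blk$conv1$bw(dy)
}

block_layers <- function(blk) list(blk$conv1, blk$conv2, blk$bn)

#' Build a dual-output U-net
#'
#' Instantiates the network described by a [unet_config()] with randomly
#' initialized (He) weights. The returned object reports its block and
#' parameter counts; parameter count grows roughly fourfold per added level.
#'
#' @param config A [unet_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `unet`.
#' @examples
#' net <- build_unet(desk_unet_config())
#' net$n_blocks
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  withr::local_seed(seed)
  d <- config$dims
  n <- config$n_levels
  ch <- config$base_channels * config$growth^(0:(n - 1L))
  down <- vector("list", n)
  up <- vector("list", n)
  pools <- lapply(seq_len(n), function(i) layer_maxpool())
  ups <- lapply(seq_len(n), function(i) layer_upsample())
  for (i in seq_len(n)) {
    in_ch <- if (i == 1L) 1L else ch[i - 1L]
    down[[i]] <- new_block(d, in_ch, ch[i], config$dropout)
  }
  for (i in seq_len(n)) {
    deep_ch <- if (i == n) ch[n] else ch[i + 1L]
    up[[i]] <- new_block(d, deep_ch + ch[i], ch[i], config$dropout)
  }
  head_seg <- layer_dense(ch[1L], 4L)
  head_diam <- layer_dense(ch[1L], 1L)
  layers <- c(
    unlist(lapply(down, block_layers), recursive = FALSE),
    unlist(lapply(up, block_layers), recursive = FALSE),
    list(head_seg, head_diam)
  )
  params <- collect_params(layers)
  n_params <- sum(vapply(params, function(p) length(p$env[[p$slot]]), 0))
  net <- structure(list(
    config = config, down = down, up = up, pools = pools, ups = ups,
    head_seg = head_seg, head_diam = head_diam,
    channels = ch, n_blocks = 2L * n, n_params = n_params
  ), class = "unet")
  net
}

#' @export
print.unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<unet> %dd, input %s, %d blocks (%d levels), channels %s, %s parameters\n",
    cfg$dims, paste(cfg$input_shape, collapse = "x"), x$n_blocks, cfg$n_levels,
    paste(x$channels, collapse = "/"), format(x$n_params, big.mark = ",")))
  invisible(x)
}

unet_layers <- function(net) {
  c(
    unlist(lapply(net$down, block_layers), recursive = FALSE),
    unlist(lapply(net$up, block_layers), recursive = FALSE),
    list(net$head_seg, net$head_diam)
  )
}

unet_params <- function(net) collect_params(unet_layers(net))

# includes batchnorm running statistics (checkpointing, not optimization)
unet_state <- function(net) collect_state(unet_layers(net))

# Forward pass. x: (N*P) x 1 matrix. Returns logits, probs, diam_pre, d_p.
unet_forward <- function(net, x, N, training = FALSE) {
  n <- net$config$n_levels
  sp <- net$config$input_shape
  skips <- vector("list", n)
  sps <- vector("list", n)
  for (i in seq_len(n)) {
    sps[[i]] <- sp
    skips[[i]] <- block_forward(net$down[[i]], x, sp, N, training)
    x <- net$pools[[i]]$fw(skips[[i]], sp, N, training)
    sp <- sp %/% 2L
  }
  for (i in rev(seq_len(n))) {
    u <- net$ups[[i]]$fw(x, sp, N, training)
    sp <- sp * 2L
    x <- block_forward(net$up[[i]], cbind(u, skips[[i]]), sp, N, training)
  }
  logits <- net$head_seg$fw(x, training)
  diam_pre <- net$head_diam$fw(x, training)
  list(logits = logits, probs = softmax_rows(logits),
       diam_pre = diam_pre, d_p = softplus(diam_pre))
}

# Backward pass given head gradients.
unet_backward <- function(net, dlogits, ddiam_pre) {
  n <- net$config$n_levels
  dx <- net$head_seg$bw(dlogits) + net$head_diam$bw(ddiam_pre)
  dskips <- vector("list", n)
  deep_ch <- function(i) if (i == net$config$n_levels) net$channels[n] else net$channels[i + 1L]
  for (i in seq_len(n)) {
    dcat <- block_backward(net$up[[i]], dx)
    dc <- deep_ch(i)
    du <- dcat[, seq_len(dc), drop = FALSE]
    dskips[[i]] <- dcat[, (dc + 1L):ncol(dcat), drop = FALSE]
    dx <- net$ups[[i]]$bw(du)
  }
  for (i in rev(seq_len(n))) {
    dh <- net$pools[[i]]$bw(dx) + dskips[[i]]
    dx <- block_backward(net$down[[i]], dh)
  }
  invisible(NULL)
}

#' Composite segmentation + diameter loss
#'
#' Per-voxel loss `L = L_CE + L_BCE + lambda * L_SE`, where `L_CE` is the
#' 4-class categorical cross-entropy of the segmentation (background counts
#' as a class), `L_BCE` is the binary cross-entropy of the dichotomized
#' background-vs-any-gut segmentation (which favors separating bowel from
#' background even when the part is ambiguous), and `L_SE` is the squared
#' error of the diameter in voxel units. Each voxel's loss is multiplied by
#' its sample weight and the result is averaged over voxels.
#'
#' @param probs `V x 4` matrix of predicted class probabilities (rows sum to
#'   1; column 1 is background).
#' @param truth Integer vector of true labels, codes 0..3.
#' @param d_p,d_t Predicted and true diameters (voxel units), length V.
#' @param weights Per-voxel sample weights, length V (default 1).
#' @param lambda Non-negative weight of the diameter term (default 0.01,
#'   which puts typical squared diameter errors on the order of the
#'   cross-entropy terms).
#' @return Scalar loss.
#' @examples
#' p <- matrix(0.25, 1, 4)
#' composite_loss(p, truth = 0L, d_p = 5, d_t = 5) # 2*log(4)
#' @export
composite_loss <- function(probs, truth, d_p, d_t, weights = NULL, lambda = 0.01) {
  if (lambda < 0) abort("`lambda` must be >= 0.")
  probs <- as.matrix(probs)
  truth <- as.integer(truth)
  V <- nrow(probs)
  stopifnot(length(truth) == V, length(d_p) == V, length(d_t) == V)
  if (is.null(weights)) weights <- rep(1, V)
  eps <- 1e-12
  p_true <- probs[cbind(seq_len(V), truth + 1L)]
  l_ce <- -log(pmax(p_true, eps))
  p0 <- probs[, 1L]
  t0 <- as.numeric(truth == 0L)
  l_bce <- -t0 * log(pmax(p0, eps)) - (1 - t0) * log(pmax(1 - p0, eps))
  l_se <- (as.numeric(d_t) - as.numeric(d_p))^2
  mean(weights * (l_ce + l_bce + lambda * l_se))
}

# gradient of composite_loss wrt logits and the diameter pre-activation
composite_loss_grad <- function(probs, truth, d_p, d_t, diam_pre, weights, lambda) {
  V <- nrow(probs)
  eps <- 1e-7
  t_onehot <- matrix(0, V, 4L)
  t_onehot[cbind(seq_len(V), truth + 1L)] <- 1
  dlogits <- probs - t_onehot
  p0 <- pmin(pmax(probs[, 1L], eps), 1 - eps)
  t0 <- as.numeric(truth == 0L)
  dl_dp0 <- -t0 / p0 + (1 - t0) / (1 - p0)
  # chain through softmax: dp0/dz_j = p0 * (delta_0j - p_j)
  dbce <- (dl_dp0 * p0) * (cbind(1, 0, 0, 0)[rep(1, V), , drop = FALSE] - probs)
  dlogits <- dlogits + dbce
  w <- weights / V
  dlogits <- dlogits * w
  ddiam_pre <- matrix(w * lambda * 2 * (as.numeric(d_p) - as.numeric(d_t)) *
                        sigmoid(as.numeric(diam_pre)), V, 1L)
  list(dlogits = dlogits, ddiam_pre = ddiam_pre)
}

# stack training samples into flat matrices for a given net
samples_to_batch <- function(samples, config) {
  sp <- config$input_shape
  check <- function(s) {
    shp <- s$grid$shape
    got <- if (config$dims == 2L) shp[1:2] else shp
    if (config$dims == 2L && shp[3L] != 1L) {
      abort("2d networks take single-slice samples (z extent 1).")
    }
    if (!identical(as.integer(got), sp)) {
      abort(sprintf("Sample shape %s does not match network input %s.",
                    paste(got, collapse = "x"), paste(sp, collapse = "x")))
    }
  }
  lapply(samples, check)
  x <- matrix(unlist(lapply(samples, function(s) as.numeric(s$image))), ncol = 1L)
  truth <- unlist(lapply(samples, function(s) as.integer(s$labels3)))
  d_t <- unlist(lapply(samples, function(s) as.numeric(s$diam_vox)))
  w <- unlist(lapply(samples, function(s) as.numeric(s$weights)))
  list(x = x, truth = truth, d_t = d_t, w = w, N = length(samples))
}

#' Train a dual-output U-net
#'
#' Full-batch training with the Adam optimizer (learning rate 1e-3 by
#' default) for a fixed number of epochs (100 by default). A fraction of the
#' samples (10% by default) is reserved for validation by a deterministic
#' seeded split, and the weights from the epoch with the lowest validation
#' loss are returned. With `val_fraction = 0` the training set doubles as the
#' validation set (useful for deliberate overfitting checks). With
#' `lambda = "auto"` the diameter weight is set from the first forward pass
#' so the diameter term lands on the same order of magnitude as the two
#' cross-entropy terms.
#'
#' @param net A [build_unet()] network.
#' @param samples List of [training_sample()]s matching the network input
#'   (single-slice samples for 2d networks).
#' @param epochs Training epochs (default 100).
#' @param lr Adam learning rate (default 1e-3).
#' @param val_fraction Fraction held out for validation (default 0.1).
#' @param lambda Diameter-term weight (>= 0), or `"auto"`.
#' @param batch_size Samples per optimizer step; `NULL` (default) trains
#'   full-batch. Smaller batches take more Adam steps per epoch, which
#'   matters for the diameter head whose outputs span tens of voxels.
#' @param seed Seed controlling the split, shuffling and dropout; fixed seeds
#'   give identical runs in single-threaded R.
#' @param verbose Print a line every 25 epochs.
#' @return An object of class `unet_fit`: `net` (best weights), `history`
#'   (tibble: epoch, train_loss, val_loss), `best_epoch`, `lambda`.
#' @export
train_unet <- function(net, samples, epochs = 100, lr = 1e-3,
                       val_fraction = 0.1, lambda = 0.01, batch_size = NULL,
                       seed = 1L, verbose = FALSE) {
  stopifnot(inherits(net, "unet"))
  if (length(samples) < 2L) abort("Need at least 2 samples.")
  withr::local_seed(seed)
  ns <- length(samples)
  if (val_fraction < 0 || val_fraction >= 1) abort("`val_fraction` must be in [0, 1).")
  if (val_fraction > 0) {
    n_val <- round(val_fraction * ns)
    if (n_val < 1L || n_val >= ns) {
      abort("`val_fraction` produces an empty training or validation split.")
    }
    val_idx <- sample.int(ns, n_val)
    train_idx <- setdiff(seq_len(ns), val_idx)
  } else {
    train_idx <- seq_len(ns)
    val_idx <- seq_len(ns)
  }
  tr_samples <- samples[train_idx]
  tr <- samples_to_batch(tr_samples, net$config)
  va <- samples_to_batch(samples[val_idx], net$config)
  params <- unet_params(net)
  state <- unet_state(net)
  opt <- adam_new(params, lr = lr)
  history <- matrix(NA_real_, epochs, 2L)
  best_val <- Inf
  best_snap <- snapshot_params(state)
  best_epoch <- 0L

  if (identical(lambda, "auto")) {
    out0 <- unet_forward(net, tr$x, tr$N, training = FALSE)
    ce_mag <- composite_loss(out0$probs, tr$truth, out0$d_p, out0$d_p,
                             tr$w, lambda = 0)
    se_mag <- mean(tr$w * (tr$d_t - as.numeric(out0$d_p))^2)
    lambda <- if (se_mag > 0) ce_mag / se_mag else 1
  }
  if (lambda < 0) abort("`lambda` must be >= 0.")

  n_tr <- length(tr_samples)
  if (is.null(batch_size) || batch_size >= n_tr) batch_size <- n_tr

  for (ep in seq_len(epochs)) {
    ord <- if (batch_size < n_tr) sample.int(n_tr) else seq_len(n_tr)
    starts <- seq(1L, n_tr, by = batch_size)
    tls <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + batch_size - 1L, n_tr)]
      bt <- if (batch_size == n_tr) tr else
        samples_to_batch(tr_samples[idx], net$config)
      out <- unet_forward(net, bt$x, bt$N, training = TRUE)
      tls[bi] <- composite_loss(out$probs, bt$truth, out$d_p, bt$d_t, bt$w, lambda)
      g <- composite_loss_grad(out$probs, bt$truth, out$d_p, bt$d_t,
                               out$diam_pre, bt$w, lambda)
      unet_backward(net, g$dlogits, g$ddiam_pre)
      opt <- adam_step(opt, params)
    }
    tl <- mean(tls)
    vout <- unet_forward(net, va$x, va$N, training = FALSE)
    vl <- composite_loss(vout$probs, va$truth, vout$d_p, va$d_t, va$w, lambda)
    history[ep, ] <- c(tl, vl)
    if (vl < best_val) {
      best_val <- vl
      best_snap <- snapshot_params(state)
      best_epoch <- ep
    }
    if (verbose && ep %% 25L == 0L) {
      message(sprintf("epoch %d: train %.4f, val %.4f", ep, tl, vl))
    }
  }
  restore_params(state, best_snap)
  structure(list(
    net = net,
    history = tibble::tibble(epoch = seq_len(epochs),
                             train_loss = history[, 1L],
                             val_loss = history[, 2L]),
    best_epoch = best_epoch, best_val_loss = best_val, lambda = lambda
  ), class = "unet_fit")
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf("<unet_fit> %d epochs, best validation loss %.5f at epoch %d\n",
              nrow(x$history), x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' @export
tidy.unet_fit <- function(x, ...) x$history

#' @export
glance.unet_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history), best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss, lambda = x$lambda,
    n_params = x$net$n_params
  )
}

#' Predict segmentation and diameter map for a scan
#'
#' Runs the network on a normalized image and returns the argmax 3-part
#' segmentation and the (non-negative) diameter map in voxel units, resized
#' back to the original scan matrix when `orig_grid` is given
#' (nearest-neighbor, matching how predictions are returned to the initial
#' CT dimensions).
#'
#' @param object A [train_unet()] fit (or a bare `unet`).
#' @param image Normalized image array matching the network input shape (2d
#'   nets accept `(nx, ny)` or `(nx, ny, 1)` arrays).
#' @param orig_grid Optional [volume_grid()] of the original scan.
#' @param ... Unused.
#' @return List with `labels` (a 3-part [label_volume()]) and `diameters`
#'   (a [diameter_map()] in voxel units).
#' @export
predict.unet_fit <- function(object, image, orig_grid = NULL, ...) {
  predict_unet(object$net, image, orig_grid)
}

#' @rdname predict.unet_fit
#' @param net A `unet`.
#' @export
predict_unet <- function(net, image, orig_grid = NULL) {
  stopifnot(inherits(net, "unet"))
  sp <- net$config$input_shape
  img <- image
  if (net$config$dims == 2L && length(dim(img)) == 3L) {
    if (dim(img)[3L] != 1L) abort("2d networks predict one slice at a time.")
    img <- img[, , 1L]
  }
  if (!identical(as.integer(dim(img)), sp)) {
    abort(sprintf("Image shape %s does not match network input %s.",
                  paste(dim(img), collapse = "x"), paste(sp, collapse = "x")))
  }
  x <- matrix(as.numeric(img), ncol = 1L)
  out <- unet_forward(net, x, 1L, training = FALSE)
  lab <- max.col(out$probs, ties.method = "first") - 1L
  dvx <- as.numeric(out$d_p)
  shp3 <- if (net$config$dims == 2L) c(sp, 1L) else sp
  net_grid <- volume_grid(shp3)
  lab_arr <- array(as.integer(lab), shp3)
  dvx_arr <- array(dvx, shp3)
  if (!is.null(orig_grid)) {
    lab_arr <- resize_array(lab_arr, orig_grid$shape, method = "nearest")
    dvx_arr <- resize_array(dvx_arr, orig_grid$shape, method = "nearest")
    net_grid <- orig_grid
  }
  list(
    labels = label_volume(array(as.integer(lab_arr), net_grid$shape), net_grid,
                          scheme = "parts3"),
    diameters = diameter_map(dvx_arr, net_grid, units = "voxels", masked = FALSE)
  )
}
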