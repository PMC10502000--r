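# Minimal neural-network engine.
#
# Activations are stored as (N * prod(spatial)) x channels matrices, rows in
# sample-major order with column-major (x-fastest) spatial order inside each
# sample. All layers are environments exposing fw(x, training) / bw(dy) and
# holding their parameters and gradients; convolutions use im2col so the
# heavy lifting is matrix multiplication. Everything is dimension-generic for
# 2d (3x3 kernels, 2x2 pooling) and 3d (3x3x3 kernels, 2x2x2 pooling).

spatial_coords <- function(sp) {
  P <- prod(sp)
  r <- 0:(P - 1L)
  if (length(sp) == 2L) {
    cbind(r %% sp[1L], r %/% sp[1L])
  } else {
    cbind(r %% sp[1L], (r %/% sp[1L]) %% sp[2L], r %/% (sp[1L] * sp[2L]))
  }
}

coords_to_row <- function(co, sp) {
  if (length(sp) == 2L) {
    co[, 1L] + co[, 2L] * sp[1L] + 1L
  } else {
    co[, 1L] + co[, 2L] * sp[1L] + co[, 3L] * sp[1L] * sp[2L] + 1L
  }
}

conv_offsets <- function(d) {
  if (d == 2L) as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  else as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
}

# per-kernel-offset gather indices into rbind(X, zero_row); length N*P each
make_conv_index <- function(sp, N) {
  d <- length(sp)
  P <- prod(sp)
  co <- spatial_coords(sp)
  offs <- conv_offsets(d)
  zero_row <- N * P + 1L
  lapply(seq_len(nrow(offs)), function(k) {
    nb <- sweep(co, 2L, offs[k, ], "+")
    valid <- rep(TRUE, P)
    for (ax in seq_len(d)) valid <- valid & nb[, ax] >= 0L & nb[, ax] <= sp[ax] - 1L
    row0 <- coords_to_row(nb, sp)
    idx <- rep((0:(N - 1L)) * P, each = P) + rep(row0, times = N)
    idx[rep(!valid, times = N)] <- zero_row
    as.integer(idx)
  })
}

layer_conv <- function(d, in_ch, out_ch) {
  e <- new.env(parent = emptyenv())
  K <- 3L^d
  e$W <- matrix(rnorm(K * in_ch * out_ch, 0, sqrt(2 / (K * in_ch))), K * in_ch, out_ch)
  e$b <- numeric(out_ch)
  e$in_ch <- in_ch; e$K <- K; e$d <- d
  e$key <- ""
  e$fw <- function(x, sp, N, training) {
    key <- paste(c(sp, N), collapse = "-")
    if (!identical(key, e$key)) {
      e$idx <- make_conv_index(sp, N)
      e$key <- key
    }
    NP <- nrow(x)
    xz <- rbind(x, 0)
    M <- matrix(0, NP, e$K * e$in_ch)
    for (k in seq_len(e$K)) {
      M[, ((k - 1L) * e$in_ch + 1L):(k * e$in_ch)] <- xz[e$idx[[k]], , drop = FALSE]
    }
    e$M <- M
    y <- M %*% e$W
    sweep(y, 2L, e$b, "+")
  }
  e$bw <- function(dy) {
    e$db <- colSums(dy)
    e$dW <- crossprod(e$M, dy)
    dM <- dy %*% t(e$W)
    NP <- nrow(dy)
    dx <- matrix(0, NP, e$in_ch)
    for (k in seq_len(e$K)) {
      idx <- e$idx[[k]]
      valid <- idx <= NP
      cols <- ((k - 1L) * e$in_ch + 1L):(k * e$in_ch)
      # each kernel offset maps distinct sources to distinct targets
      dx[idx[valid], ] <- dx[idx[valid], , drop = FALSE] + dM[valid, cols, drop = FALSE]
    }
    e$M <- NULL
    dx
  }
  e
}

layer_dense <- function(in_ch, out_ch) {
  e <- new.env(parent = emptyenv())
  e$W <- matrix(rnorm(in_ch * out_ch, 0, sqrt(2 / in_ch)), in_ch, out_ch)
  e$b <- numeric(out_ch)
  e$fw <- function(x, training) {
    e$x <- x
    sweep(x %*% e$W, 2L, e$b, "+")
  }
  e$bw <- function(dy) {
    e$db <- colSums(dy)
    e$dW <- crossprod(e$x, dy)
    dx <- dy %*% t(e$W)
    e$x <- NULL
    dx
  }
  e
}

layer_relu <- function() {
  e <- new.env(parent = emptyenv())
  e$fw <- function(x, training) {
    e$mask <- x > 0
    x * e$mask
  }
  e$bw <- function(dy) {
    dx <- dy * e$mask
    e$mask <- NULL
    dx
  }
  e
}

layer_bn <- function(ch, momentum = 0.9, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$gamma <- rep(1, ch)
  e$beta <- rep(0, ch)
  e$run_mean <- rep(0, ch)
  e$run_var <- rep(1, ch)
  e$fw <- function(x, training) {
    if (training) {
      mu <- colMeans(x)
      v <- colMeans(x * x) - mu^2
      v <- pmax(v, 0)
      e$run_mean <- momentum * e$run_mean + (1 - momentum) * mu
      e$run_var <- momentum * e$run_var + (1 - momentum) * v
    } else {
      mu <- e$run_mean
      v <- e$run_var
    }
    ivar <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(x, 2L, mu, "-"), 2L, ivar, "*")
    if (training) {
      e$xhat <- xhat
      e$ivar <- ivar
    }
    sweep(sweep(xhat, 2L, e$gamma, "*"), 2L, e$beta, "+")
  }
  e$bw <- function(dy) {
    n <- nrow(dy)
    e$dgamma <- colSums(dy * e$xhat)
    e$dbeta <- colSums(dy)
    dxhat <- sweep(dy, 2L, e$gamma, "*")
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * e$xhat)
    dx <- sweep(dxhat, 2L, s1 / n, "-") - sweep(e$xhat, 2L, s2 / n, "*")
    dx <- sweep(dx, 2L, e$ivar, "*")
    e$xhat <- NULL
    dx
  }
  e
}

layer_dropout <- function(rate) {
  e <- new.env(parent = emptyenv())
  e$rate <- rate
  e$fw <- function(x, training) {
    if (!training || e$rate <= 0) {
      e$mask <- NULL
      return(x)
    }
    e$mask <- matrix((runif(length(x)) >= e$rate) / (1 - e$rate), nrow(x), ncol(x))
    x * e$mask
  }
  e$bw <- function(dy) {
    if (is.null(e$mask)) return(dy)
    dx <- dy * e$mask
    e$mask <- NULL
    dx
  }
  e
}

# 2x (per axis) max pooling
layer_maxpool <- function() {
  e <- new.env(parent = emptyenv())
  e$key <- ""
  e$fw <- function(x, sp, N, training) {
    d <- length(sp)
    key <- paste(c(sp, N), collapse = "-")
    if (!identical(key, e$key)) {
      out_sp <- sp %/% 2L
      co <- spatial_coords(out_sp)
      offs <- conv_offsets(d)
      offs <- offs[apply(offs >= 0, 1L, all) & apply(offs <= 1, 1L, all), , drop = FALSE]
      P <- prod(sp); Po <- prod(out_sp)
      e$cand <- lapply(seq_len(nrow(offs)), function(k) {
        child <- sweep(co * 2L, 2L, offs[k, ], "+")
        row0 <- coords_to_row(child, sp)
        as.integer(rep((0:(N - 1L)) * P, each = Po) + rep(row0, times = N))
      })
      e$in_rows <- N * P
      e$key <- key
    }
    best <- x[e$cand[[1L]], , drop = FALSE]
    besti <- matrix(e$cand[[1L]], nrow(best), ncol(best))
    for (k in 2:length(e$cand)) {
      candi <- e$cand[[k]]
      cand <- x[candi, , drop = FALSE]
      upd <- cand > best
      best[upd] <- cand[upd]
      besti[upd] <- matrix(candi, nrow(best), ncol(best))[upd]
    }
    e$besti <- besti
    best
  }
  e$bw <- function(dy) {
    dx <- matrix(0, e$in_rows, ncol(dy))
    for (c in seq_len(ncol(dy))) {
      dx[e$besti[, c], c] <- dy[, c]
    }
    e$besti <- NULL
    dx
  }
  e
}

# nearest-neighbor 2x upsampling
layer_upsample <- function() {
  e <- new.env(parent = emptyenv())
  e$key <- ""
  e$fw <- function(x, sp, N, training) {
    # sp is the *input* spatial shape
    key <- paste(c(sp, N), collapse = "-")
    if (!identical(key, e$key)) {
      out_sp <- sp * 2L
      co <- spatial_coords(out_sp)
      parent0 <- coords_to_row(co %/% 2L, sp)
      P <- prod(sp); Po <- prod(out_sp)
      e$pidx <- as.integer(rep((0:(N - 1L)) * P, each = Po) + rep(parent0, times = N))
      e$key <- key
    }
    x[e$pidx, , drop = FALSE]
  }
  e$bw <- function(dy) {
    rowsum(dy, e$pidx)
  }
  e
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- Adam optimizer over a flat parameter registry --------------------------

param_slots <- function(layer) {
  slots <- intersect(c("W", "b", "gamma", "beta"), ls(layer))
  slots
}

collect_params <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) {
    for (s in param_slots(layers[[i]])) {
      out[[length(out) + 1L]] <- list(env = layers[[i]], slot = s)
    }
  }
  out
}

# trainable parameters plus batchnorm running statistics: everything a
# checkpoint must capture for inference to match the saved epoch
collect_state <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) {
    for (s in intersect(c("W", "b", "gamma", "beta", "run_mean", "run_var"),
                        ls(layers[[i]]))) {
      out[[length(out) + 1L]] <- list(env = layers[[i]], slot = s)
    }
  }
  out
}

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
             m = lapply(params, function(p) p$env[[p$slot]] * 0),
             v = lapply(params, function(p) p$env[[p$slot]] * 0))
  st
}

adam_step <- function(st, params) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$env[[paste0("d", p$slot)]]
    if (is.null(g)) next
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    mhat <- st$m[[i]] / (1 - b1^st$t)
    vhat <- st$v[[i]] / (1 - b2^st$t)
    p$env[[p$slot]] <- p$env[[p$slot]] - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  st
}

snapshot_params <- function(params) {
  lapply(params, function(p) p$env[[p$slot]])
}

restore_params <- function(params, snap) {
  for (i in seq_along(params)) params[[i]]$env[[params[[i]]$slot]] <- snap[[i]]
  invisible(NULL)
}
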