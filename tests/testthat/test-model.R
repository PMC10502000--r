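test_that("network topology matches its configuration", {
  cfg2 <- unet_config(dims = 2)
  expect_equal(cfg2$n_levels, 7L)
  expect_equal(cfg2$base_channels, 8L)
  net2 <- build_unet(cfg2)
  expect_equal(net2$n_blocks, 14L) # 256 halved 7 times reaches the 2x2 midpoint
  expect_equal(prod(cfg2$input_shape %/% 2L^cfg2$n_levels), 4L)

  cfg3 <- unet_config(dims = 3)
  net3 <- build_unet(cfg3)
  expect_equal(net3$n_blocks, 10L)
  expect_equal(cfg3$input_shape %/% 2L^cfg3$n_levels, c(4L, 4L, 2L))

  expect_error(unet_config(dims = 2, input_shape = c(100, 100), n_levels = 3),
               "divisible")
})

test_that("parameter count grows roughly fourfold per level", {
  n3 <- build_unet(unet_config(dims = 2, input_shape = c(64, 64),
                               base_channels = 4, n_levels = 3))$n_params
  n4 <- build_unet(unet_config(dims = 2, input_shape = c(64, 64),
                               base_channels = 4, n_levels = 4))$n_params
  ratio <- n4 / n3
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 5)
})

test_that("descending levels halve the spatial dimensions", {
  cfg <- desk_unet_config()
  net <- build_unet(cfg, seed = 2)
  x <- matrix(rnorm(64 * 64), ncol = 1)
  sp <- cfg$input_shape
  h <- gutgaze:::block_forward(net$down[[1]], x, sp, 1L, FALSE)
  p <- net$pools[[1]]$fw(h, sp, 1L, FALSE)
  expect_equal(nrow(h), 64 * 64)
  expect_equal(nrow(p), 32 * 32)
  expect_equal(ncol(h), net$channels[1])
})

test_that("the composite loss matches analytic values and a scalar-loop oracle", {
  # perfect one-hot prediction with exact diameter gives zero loss
  p_perf <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 0))
  expect_equal(composite_loss(p_perf, c(0L, 2L), d_p = c(3, 4), d_t = c(3, 4)), 0,
               tolerance = 1e-9)
  # uniform prediction on true background: ln4 (CE) + ln4 (BCE)
  expect_equal(composite_loss(matrix(0.25, 1, 4), 0L, d_p = 7, d_t = 7),
               2 * log(4), tolerance = 1e-12)
  # the diameter term adds lambda * (d_t - d_p)^2
  match_cls <- matrix(c(1, 0, 0, 0), 1)
  expect_equal(composite_loss(match_cls, 0L, d_p = 0, d_t = 10, lambda = 0.01),
               1, tolerance = 1e-9)
  expect_error(composite_loss(match_cls, 0L, 1, 1, lambda = -1), ">= 0")

  # independent per-voxel scalar loop
  for (s in 1:3) {
    withr::with_seed(s, {
      V <- 50
      z <- matrix(rnorm(V * 4), V)
      probs <- exp(z) / rowSums(exp(z))
      truth <- sample(0:3, V, TRUE)
      d_t <- runif(V, 0, 20)
      d_p <- runif(V, 0, 20)
      w <- sample(c(1, 10), V, TRUE)
      lambda <- runif(1, 0, 0.2)
    })
    acc <- 0
    for (v in seq_len(V)) {
      tk <- numeric(4); tk[truth[v] + 1] <- 1
      l_ce <- -sum(tk * log(probs[v, ]))
      t0 <- tk[1]
      l_bce <- -t0 * log(probs[v, 1]) - (1 - t0) * log(1 - probs[v, 1])
      l_se <- (d_t[v] - d_p[v])^2
      acc <- acc + w[v] * (l_ce + l_bce + lambda * l_se)
    }
    expect_equal(composite_loss(probs, truth, d_p, d_t, w, lambda), acc / V,
                 tolerance = 1e-5)
  }
})

test_that("loss gradients match numerical differentiation", {
  withr::with_seed(4, {
    V <- 12
    z <- matrix(rnorm(V * 4), V)
    truth <- sample(0:3, V, TRUE)
    pre <- rnorm(V, 2, 1)
    d_t <- runif(V, 0, 10)
    w <- sample(c(1, 10), V, TRUE)
  })
  lambda <- 0.05
  loss_of <- function(z, pre) {
    probs <- exp(z - apply(z, 1, max)) / rowSums(exp(z - apply(z, 1, max)))
    composite_loss(probs, truth, gutgaze:::softplus(pre), d_t, w, lambda)
  }
  probs <- exp(z - apply(z, 1, max)) / rowSums(exp(z - apply(z, 1, max)))
  g <- gutgaze:::composite_loss_grad(probs, truth, gutgaze:::softplus(pre),
                                     d_t, pre, w, lambda)
  h <- 1e-6
  for (v in c(1, 5, 9)) for (j in 1:4) {
    zp <- z; zp[v, j] <- zp[v, j] + h
    zm <- z; zm[v, j] <- zm[v, j] - h
    expect_equal(g$dlogits[v, j], (loss_of(zp, pre) - loss_of(zm, pre)) / (2 * h),
                 tolerance = 1e-4)
  }
  for (v in c(2, 7)) {
    pp <- pre; pp[v] <- pp[v] + h
    pm <- pre; pm[v] <- pm[v] - h
    expect_equal(g$ddiam_pre[v, 1], (loss_of(z, pp) - loss_of(z, pm)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("with lambda 0 the diameter error contributes no gradient", {
  withr::with_seed(5, {
    V <- 20
    probs <- matrix(runif(V * 4, 0.1, 1), V)
    probs <- probs / rowSums(probs)
    truth <- sample(0:3, V, TRUE)
    pre <- rnorm(V)
  })
  g <- gutgaze:::composite_loss_grad(probs, truth, gutgaze:::softplus(pre),
                                     runif(V, 0, 10), pre, rep(1, V), 0)
  expect_true(all(g$ddiam_pre == 0))
})

test_that("training is deterministic and records its best epoch", {
  slices <- make_training_slices(seed = 7, n_slices = 4)
  cfg <- desk_unet_config()
  fit1 <- train_unet(build_unet(cfg, seed = 1), slices, epochs = 4,
                     val_fraction = 0.25, seed = 3)
  fit2 <- train_unet(build_unet(cfg, seed = 1), slices, epochs = 4,
                     val_fraction = 0.25, seed = 3)
  expect_identical(fit1$history, fit2$history)
  expect_true(fit1$best_epoch >= 1 && fit1$best_epoch <= 4)
  expect_equal(min(fit1$history$val_loss), fit1$best_val_loss)
  expect_error(train_unet(build_unet(cfg), slices[1:2], val_fraction = 0.1),
               "empty")
  expect_error(train_unet(build_unet(cfg), slices[1], epochs = 1), "at least 2")
})

test_that("the loss decreases while overfitting a single batch", {
  slices <- make_training_slices(seed = 7, n_slices = 2)
  fit <- train_unet(build_unet(desk_unet_config(), seed = 1), slices,
                    epochs = 15, lr = 5e-3, val_fraction = 0, seed = 1)
  h <- fit$history$train_loss
  expect_lt(mean(h[13:15]), mean(h[1:3]))
})

test_that("predictions respect the output contracts", {
  slices <- make_training_slices(seed = 7, n_slices = 2)
  net <- build_unet(desk_unet_config(), seed = 6)
  pred <- predict_unet(net, slices[[1]]$image)
  expect_s3_class(pred$labels, "label_volume")
  expect_true(all(pred$labels$values %in% 0:3))
  expect_true(all(pred$diameters$values >= 0))
  expect_equal(pred$diameters$units, "voxels")
  # resized back to an original matrix
  og <- volume_grid(c(128, 128, 1))
  pred2 <- predict_unet(net, slices[[1]]$image, orig_grid = og)
  expect_equal(dim(pred2$labels$values), c(128L, 128L, 1L))
  expect_true(all(pred2$labels$values %in% 0:3))
  expect_error(predict_unet(net, array(0, c(32, 32))), "does not match")
})

test_that("auto lambda balances the diameter term's order of magnitude", {
  slices <- make_training_slices(seed = 7, n_slices = 2)
  fit <- train_unet(build_unet(desk_unet_config(), seed = 1), slices,
                    epochs = 1, val_fraction = 0, lambda = "auto", seed = 1)
  expect_gt(fit$lambda, 0)
  expect_true(is.finite(fit$lambda))
})
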