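#' Plot an axial slice of a volume with optional label overlay
#'
#' @param values HU or intensity array (or a `phantom_volume`, whose CT is
#'   used).
#' @param slice Slice index along z.
#' @param labels Optional [label_volume()] overlaid with transparency.
#' @return A ggplot.
#' @export
plot_slice <- function(values, slice = 1L, labels = NULL) {
  if (inherits(values, "phantom_volume")) {
    if (is.null(labels)) labels <- values$truth_labels
    values <- values$ct
  }
  sl <- values[, , slice]
  df <- tidyr::expand_grid(y = seq_len(ncol(sl)), x = seq_len(nrow(sl)))
  df$value <- as.numeric(sl)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                         fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "HU", title = sprintf("Slice %d", slice))
  if (!is.null(labels)) {
    lv <- labels$values[, , slice]
    ldf <- df
    ldf$label <- factor(as.integer(lv))
    ldf <- ldf[ldf$label != "0", , drop = FALSE]
    if (nrow(ldf)) {
      gg <- gg + ggplot2::geom_raster(
        data = ldf,
        ggplot2::aes(x = .data$x, y = .data$y),
        fill = c("red", "yellow", "green", "blue", "orange", "purple",
                 "cyan", "magenta", "brown", "pink", "darkgreen", "navy",
                 "gray")[as.integer(as.character(ldf$label))],
        alpha = 0.4, inherit.aes = FALSE)
    }
  }
  gg
}

#' Plot the training history of a U-net fit
#'
#' @param object A [train_unet()] fit.
#' @param ... Unused.
#' @return A ggplot of train/validation loss by epoch.
#' @export
autoplot.unet_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::labs(title = "Training history", y = "Composite loss")
}
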