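## broom-style tidiers and ggplot2 helpers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the VQ-VAE training log
#'
#' @param x An `lh_vqvae`.
#' @param ... Unused.
#' @return Tibble with one row per epoch and loss term (long format).
#' @method tidy lh_vqvae
#' @export
tidy.lh_vqvae <- function(x, ...) {
  log <- x$log
  out <- lapply(c("train_recons", "train_commit", "val_recons", "val_commit"),
                function(nm) {
                  tibble::tibble(epoch = log$epoch, term = nm,
                                 loss = log[[nm]])
                })
  do.call(rbind, out)
}

#' @rdname tidy.lh_vqvae
#' @method glance lh_vqvae
#' @export
glance.lh_vqvae <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(epochs = last$epoch, K = x$config$K, n_z = x$config$n_z,
                 f = x$config$f, train_recons = last$train_recons,
                 val_recons = last$val_recons,
                 val_commit = last$val_commit)
}

#' Tidy a density model's training log
#'
#' @param x An `lh_density`.
#' @param ... Unused.
#' @return One-row tibble with the held-out NLL before and after fitting.
#' @method glance lh_density
#' @export
glance.lh_density <- function(x, ...) {
  out <- x$log %||% tibble::tibble(n_train = 0L, n_val = 0L,
                                   nll_initial = x$d * log(x$K),
                                   nll_heldout = NA_real_)
  out$K <- x$K
  out$d <- x$d
  out$context_order <- x$context_order
  out
}

#' Plot the VQ-VAE training curves
#'
#' @param object An `lh_vqvae`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lh_vqvae
#' @export
autoplot.lh_vqvae <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)",
                  title = "VQ-VAE training") +
    ggplot2::theme_minimal()
}

#' Plot an image, residual map or mask as a raster
#'
#' @param x Numeric matrix (2D only).
#' @param title Optional plot title.
#' @return A ggplot.
#' @importFrom rlang .data
#' @export
plot_image <- function(x, title = NULL) {
  stopifnot(length(img_dim(x)) == 2L)
  d <- dim(x)
  df <- data.frame(row = rep(seq_len(d[1]), d[2]),
                   col = rep(seq_len(d[2]), each = d[1]),
                   value = as.vector(x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, NA)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot a segmentation result (input, healed, residual)
#'
#' @param segmentation An `lh_segmentation`.
#' @param image The input image it was computed from.
#' @return A ggplot of the mask-filtered residual map.
#' @export
plot_segmentation <- function(segmentation, image = NULL) {
  stopifnot(inherits(segmentation, "lh_segmentation"))
  plot_image(segmentation$residual, title = "mask-filtered residual")
}
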