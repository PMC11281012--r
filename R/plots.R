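# ggplot2 presentation methods for the tabular result types.

#' Plot a confidence sweep (P/R/F1 against confidence threshold)
#'
#' @param object an `rgbdet_sweep` from [confidence_sweep()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rgbdet_sweep <- function(object, ...) {
  df <- tidyr_longer(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "confidence threshold", y = NULL, colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

# minimal long-format pivot (precision/recall/f1) without a tidyr dependency
tidyr_longer <- function(sweep) {
  dplyr::bind_rows(lapply(c("precision", "recall", "f1"), function(m)
    tibble::tibble(threshold = sweep$threshold, metric = m,
                   value = sweep[[m]])))
}

#' Plot an evaluation report: AP per class across the IoU ladder
#'
#' @param object an `rgbdet_eval` from [eval_detections()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rgbdet_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_class,
                  ggplot2::aes(x = .data$iou_thr, y = .data$ap,
                               colour = factor(.data$class_id))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "IoU threshold", y = "average precision",
                  colour = "class") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a training log (loss components per epoch, mosaic phase marked)
#'
#' @param object an `rgbdet_train_log` from [train_model()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rgbdet_train_log <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(
    c(total = "loss", objectness = "loss_obj", class = "loss_cls",
      box = "loss_box"),
    function(col) tibble::tibble(epoch = object$epoch, value = object[[col]])),
    .id = "component")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                        colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
  off <- object$epoch[!object$mosaic]
  if (length(off) > 0L)
    p <- p + ggplot2::geom_vline(xintercept = min(off), linetype = "dashed")
  p
}

#' Render detections over an RGB raster
#'
#' @param pair an `image_pair`.
#' @param boxes box tibble from [predict_pair()].
#' @return a ggplot object showing the RGB image with box overlays.
#' @export
plot_detections <- function(pair, boxes) {
  h <- nrow(pair$depth); w <- ncol(pair$depth)
  rgb <- pair$rgb
  df <- expand.grid(y = seq_len(h), x = seq_len(w))
  df$fill <- grDevices::rgb(rgb[, , 1], rgb[, , 2], rgb[, , 3])
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_rect(data = boxes,
                       ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                                    ymin = .data$y_min, ymax = .data$y_max),
                       colour = "yellow", fill = NA, linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
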