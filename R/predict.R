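# Decoding raw head maps into boxes, non-maximum suppression, and
# checkpoint-driven prediction.

# Decode one image's per-scale prediction arrays into a box tibble.
decode_predictions <- function(preds, num_classes, strides = c(8L, 16L, 32L),
                               conf_thr = 0.25, image = 1L) {
  rows <- list()
  for (k in seq_along(preds)) {
    p <- preds[[k]]
    s <- strides[k]
    d <- dim(p)
    gh <- d[3]; gw <- d[4]
    obj <- sigm(p[image, 5, , ])
    for (gi in seq_len(gh)) for (gj in seq_len(gw)) {
      # confidence is the objectness alone: class logits are supervised only
      # at positive cells, so they carry no ranking signal elsewhere
      conf <- obj[gi, gj]
      if (conf < conf_thr) next
      cls_logit <- p[image, 5 + seq_len(num_classes), gi, gj]
      ci <- which.max(sigm(cls_logit))
      px <- (2 * sigm(p[image, 1, gi, gj]) - 0.5 + gj - 1) * s
      py <- (2 * sigm(p[image, 2, gi, gj]) - 0.5 + gi - 1) * s
      # floor the decoded extent so saturated logits cannot emit a
      # degenerate zero-area box
      pw <- max(1e-3, (2 * sigm(p[image, 3, gi, gj]))^2 * BOX_SIZE_MULT * s)
      ph <- max(1e-3, (2 * sigm(p[image, 4, gi, gj]))^2 * BOX_SIZE_MULT * s)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        x_min = px - pw / 2, y_min = py - ph / 2,
        x_max = px + pw / 2, y_max = py + ph / 2,
        class_id = ci - 1L, confidence = conf)
    }
  }
  if (length(rows) == 0L)
    return(tibble::tibble(x_min = numeric(), y_min = numeric(),
                          x_max = numeric(), y_max = numeric(),
                          class_id = integer(), confidence = numeric()))
  dplyr::bind_rows(rows)
}

#' Non-maximum suppression
#'
#' Greedy per-class suppression: keep the highest-confidence box, drop any
#' remaining box of the same class overlapping it above `iou_thr`.
#'
#' @param boxes box tibble with confidence and class_id.
#' @param iou_thr suppression IoU threshold (default 0.5).
#' @return filtered box tibble.
#' @export
nms_boxes <- function(boxes, iou_thr = 0.5) {
  if (nrow(boxes) <= 1L) return(boxes)
  keep_rows <- list()
  for (cl in unique(boxes$class_id)) {
    bx <- boxes[boxes$class_id == cl, , drop = FALSE]
    bx <- bx[order(-bx$confidence), , drop = FALSE]
    alive <- rep(TRUE, nrow(bx))
    for (i in seq_len(nrow(bx))) {
      if (!alive[i]) next
      if (i < nrow(bx)) for (j in (i + 1L):nrow(bx)) {
        if (!alive[j]) next
        iou <- box_iou(c(bx$x_min[i], bx$y_min[i], bx$x_max[i], bx$y_max[i]),
                       c(bx$x_min[j], bx$y_min[j], bx$x_max[j], bx$y_max[j]))
        if (iou > iou_thr) alive[j] <- FALSE
      }
    }
    keep_rows[[length(keep_rows) + 1L]] <- bx[alive, , drop = FALSE]
  }
  out <- dplyr::bind_rows(keep_rows)
  out[order(-out$confidence), , drop = FALSE]
}

pair_to_inputs <- function(pair) {
  rgb <- aperm(pair$rgb, c(3, 1, 2))
  dim(rgb) <- c(1L, dim(rgb))
  depth <- pair$depth
  dim(depth) <- c(1L, 1L, dim(depth))
  ir <- NULL
  if (!is.null(pair$ir)) {
    ir <- pair$ir
    dim(ir) <- c(1L, 1L, dim(ir))
  }
  list(rgb = rgb, depth = depth, ir = ir)
}

#' Detect objects in one aligned image pair
#'
#' Runs the forward pass, decodes the per-scale maps, filters by
#' confidence, and applies non-maximum suppression. Deterministic given the
#' model weights.
#'
#' @param model an `rgbdet_model`.
#' @param pair an `image_pair` (aligned rgb/depth, optional ir).
#' @param conf_thr confidence threshold (default 0.25).
#' @param nms_iou NMS IoU threshold (default 0.5).
#' @return box tibble in pixel coordinates.
#' @export
predict_pair <- function(model, pair, conf_thr = 0.25, nms_iou = 0.5) {
  inp <- pair_to_inputs(pair)
  if (!identical(dim(inp$rgb)[3:4], dim(inp$depth)[3:4]))
    stopf("pair is not aligned")
  preds <- forward_model(model, inp$rgb, inp$depth, inp$ir)
  boxes <- decode_predictions(preds, model$config$num_classes,
                              model$config$strides, conf_thr)
  nms_boxes(boxes, nms_iou)
}

labels_to_boxes <- function(labels, h, w, image = 1L) {
  tibble::tibble(
    image = image,
    x_min = (labels$xc - labels$w / 2) * w,
    y_min = (labels$yc - labels$h / 2) * h,
    x_max = (labels$xc + labels$w / 2) * w,
    y_max = (labels$yc + labels$h / 2) * h,
    class_id = labels$class_id)
}

#' Evaluate a model over a list of image pairs
#'
#' @param model an `rgbdet_model`.
#' @param pairs list of `image_pair` objects.
#' @param conf_thr,nms_iou prediction thresholds.
#' @return an `rgbdet_eval` report.
#' @export
evaluate_pairs <- function(model, pairs, conf_thr = 0.05, nms_iou = 0.5) {
  all_preds <- list(); all_gts <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    bx <- predict_pair(model, p, conf_thr, nms_iou)
    if (nrow(bx) > 0L) {
      bx$image <- i
      all_preds[[length(all_preds) + 1L]] <- bx
    }
    gt <- labels_to_boxes(p$labels, nrow(p$depth), ncol(p$depth), image = i)
    if (nrow(gt) > 0L) all_gts[[length(all_gts) + 1L]] <- gt
  }
  preds <- if (length(all_preds)) dplyr::bind_rows(all_preds)
           else tibble::tibble(image = integer(), x_min = numeric(),
                               y_min = numeric(), x_max = numeric(),
                               y_max = numeric(), class_id = integer(),
                               confidence = numeric())
  gts <- dplyr::bind_rows(all_gts)
  eval_detections(preds, gts)
}
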