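# Detection evaluation: IoU matching, precision/recall, average precision,
# mAP50 / mAP50:95, and confidence sweeps.
#
# Boxes travel as tibbles with pixel corner coordinates (x_min, y_min,
# x_max, y_max), class_id, an image identifier, and (for predictions) a
# confidence in [0, 1].

#' Intersection over union of two axis-aligned boxes
#'
#' @param a,b numeric vectors `(x_min, y_min, x_max, y_max)` (extra fields
#'   ignored); degenerate boxes (non-positive extent) are rejected.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes.
#' @export
box_iou <- function(a, b) {
  a <- as.numeric(a[1:4]); b <- as.numeric(b[1:4])
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2])
    stopf("degenerate box: x_max/y_max must exceed x_min/y_min")
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

iou_matrix <- function(preds, gts) {
  m <- matrix(0, nrow(preds), nrow(gts))
  for (i in seq_len(nrow(preds)))
    for (j in seq_len(nrow(gts)))
      m[i, j] <- box_iou(c(preds$x_min[i], preds$y_min[i],
                           preds$x_max[i], preds$y_max[i]),
                         c(gts$x_min[j], gts$y_min[j],
                           gts$x_max[j], gts$y_max[j]))
  m
}

#' Greedy confidence-ordered matching of predictions to ground truths
#'
#' Predictions are sorted by descending confidence; each is matched to the
#' highest-IoU not-yet-matched ground truth of the same class (and image,
#' when an `image` column is present) with IoU strictly above the
#' threshold. Matched predictions are true positives, unmatched predictions
#' false positives, unmatched ground truths false negatives.
#'
#' @param preds,gts box tibbles (see module docs).
#' @param iou_thr IoU threshold (strict `>` comparison).
#' @return list with counts `tp`, `fp`, `fn` and the per-prediction tibble
#'   `flags` (confidence order) with a logical `tp` column.
#' @export
match_detections <- function(preds, gts, iou_thr = 0.5) {
  np <- if (is.null(preds)) 0L else nrow(preds)
  ng <- if (is.null(gts)) 0L else nrow(gts)
  if (np == 0L)
    return(list(tp = 0L, fp = 0L, fn = ng,
                flags = tibble::tibble(confidence = numeric(), tp = logical())))
  ord <- order(-preds$confidence)
  preds <- preds[ord, , drop = FALSE]
  matched <- rep(FALSE, ng)
  tp_flag <- rep(FALSE, np)
  has_img <- ng > 0L && "image" %in% names(preds) && "image" %in% names(gts)
  if (ng > 0L) {
    iom <- iou_matrix(preds, gts)
    for (i in seq_len(np)) {
      cand <- which(!matched & gts$class_id == preds$class_id[i] &
                      iom[i, ] > iou_thr)
      if (has_img) cand <- cand[gts$image[cand] == preds$image[i]]
      if (length(cand) == 0L) next
      j <- cand[which.max(iom[i, cand])]
      matched[j] <- TRUE
      tp_flag[i] <- TRUE
    }
  }
  list(tp = sum(tp_flag), fp = sum(!tp_flag), fn = sum(!matched),
       flags = tibble::tibble(confidence = preds$confidence, tp = tp_flag))
}

#' Precision and recall from match counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`; both defined as
#' 0 when the denominator is 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @return a rate in `[0, 1]`.
#' @export
precision <- function(tp, fp) if (tp + fp == 0) 0 else tp / (tp + fp)

#' @rdname precision
#' @export
recall <- function(tp, fn) if (tp + fn == 0) 0 else tp / (tp + fn)

#' Average precision for one class
#'
#' `method = "standard"` (default) sweeps the confidence ranking and
#' integrates the all-point-interpolated precision-recall curve — the AP
#' that mAP50 / mAP50:95 conventionally denote. `method = "accuracy"` is
#' the accuracy-style ratio `(TP + TN) / (TP + TN + FP + FN)` at the fixed
#' operating point of all predictions, with TN taken as 0 (true negatives
#' are undefined for detection); retained as a documented alternative.
#'
#' @param preds,gts single-class box tibbles; predictions carry confidences.
#' @param iou_thr IoU threshold.
#' @param method `"standard"` or `"accuracy"`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(preds, gts, iou_thr = 0.5,
                              method = c("standard", "accuracy")) {
  method <- match.arg(method)
  mt <- match_detections(preds, gts, iou_thr)
  if (method == "accuracy") {
    denom <- mt$tp + mt$fp + mt$fn       # + TN = 0
    return(if (denom == 0) 0 else mt$tp / denom)
  }
  ng <- if (is.null(gts)) 0L else nrow(gts)
  if (ng == 0L || nrow(mt$flags) == 0L) return(0)
  tp_cum <- cumsum(mt$flags$tp)
  fp_cum <- cumsum(!mt$flags$tp)
  rec <- tp_cum / ng
  prec <- tp_cum / (tp_cum + fp_cum)
  # all-point interpolation: envelope precision, integrate over recall steps
  mrec <- c(0, rec, 1)
  mpre <- c(0, prec, 0)
  for (i in rev(seq_len(length(mpre) - 1L)))
    mpre[i] <- max(mpre[i], mpre[i + 1L])
  idx <- which(mrec[-1] != mrec[-length(mrec)])
  sum((mrec[idx + 1L] - mrec[idx]) * mpre[idx + 1L])
}

#' Mean average precision over classes
#'
#' @param per_class_ap named numeric vector (or list) of per-class APs.
#' @return unweighted mean; an empty class set is rejected.
#' @export
mean_ap <- function(per_class_ap) {
  v <- unlist(per_class_ap)
  if (length(v) == 0L) stopf("mean_ap needs at least one class")
  mean(v)
}

ap_by_class <- function(preds, gts, iou_thr, classes) {
  vapply(classes, function(cl) {
    average_precision(preds[preds$class_id == cl, , drop = FALSE],
                      gts[gts$class_id == cl, , drop = FALSE], iou_thr)
  }, numeric(1))
}

#' mAP averaged over the IoU ladder 0.50 to 0.95
#'
#' Mean over classes of AP, itself averaged over the ten IoU thresholds
#' `0.50, 0.55, ..., 0.95` (step 0.05).
#'
#' @param preds,gts box tibbles.
#' @return list with `map50`, `map50_95`, and the per-threshold tibble.
#' @export
map50_95 <- function(preds, gts) {
  classes <- sort(unique(gts$class_id))
  if (length(classes) == 0L) stopf("no ground-truth classes to evaluate")
  thrs <- seq(0.5, 0.95, by = 0.05)
  per_thr <- vapply(thrs, function(t) mean(ap_by_class(preds, gts, t, classes)),
                    numeric(1))
  list(map50 = per_thr[1], map50_95 = mean(per_thr),
       per_threshold = tibble::tibble(iou_thr = thrs, map = per_thr))
}

#' Precision/recall/F1 across confidence thresholds
#'
#' Filters predictions at each confidence threshold, recomputes the counts
#' at the given IoU threshold, and reports the best-F1 operating point.
#'
#' @param preds,gts box tibbles.
#' @param thresholds confidence thresholds to sweep.
#' @param iou_thr IoU threshold for matching.
#' @return tibble (threshold, tp, fp, fn, precision, recall, f1) with the
#'   best-F1 row index in attribute `best`.
#' @export
confidence_sweep <- function(preds, gts, thresholds = seq(0, 1, by = 0.05),
                             iou_thr = 0.5) {
  rows <- lapply(thresholds, function(t) {
    keep <- preds[preds$confidence >= t, , drop = FALSE]
    mt <- match_detections(keep, gts, iou_thr)
    p <- precision(mt$tp, mt$fp); r <- recall(mt$tp, mt$fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    tibble::tibble(threshold = t, tp = mt$tp, fp = mt$fp, fn = mt$fn,
                   precision = p, recall = r, f1 = f1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "best") <- which.max(out$f1)
  class(out) <- c("rgbdet_sweep", class(out))
  out
}

#' Full evaluation report
#'
#' Per-class AP on the IoU ladder, mAP50, mAP50:95, and the best-F1
#' confidence operating point.
#'
#' @param preds,gts box tibbles (pixel corners, class_id, image,
#'   confidence for predictions).
#' @param conf_thresholds thresholds for the confidence sweep.
#' @return an `rgbdet_eval` object.
#' @export
eval_detections <- function(preds, gts,
                            conf_thresholds = seq(0, 1, by = 0.05)) {
  classes <- sort(unique(gts$class_id))
  if (length(classes) == 0L) stopf("no ground-truth classes to evaluate")
  thrs <- seq(0.5, 0.95, by = 0.05)
  per_class <- dplyr::bind_rows(lapply(thrs, function(t) {
    ap <- ap_by_class(preds, gts, t, classes)
    rows <- lapply(seq_along(classes), function(i) {
      cl <- classes[i]
      mt <- match_detections(preds[preds$class_id == cl, , drop = FALSE],
                             gts[gts$class_id == cl, , drop = FALSE], t)
      p <- precision(mt$tp, mt$fp); r <- recall(mt$tp, mt$fn)
      tibble::tibble(class_id = cl, iou_thr = t, ap = ap[i],
                     tp = mt$tp, fp = mt$fp, fn = mt$fn,
                     precision = p, recall = r,
                     f1 = if (p + r == 0) 0 else 2 * p * r / (p + r))
    })
    dplyr::bind_rows(rows)
  }))
  maps <- map50_95(preds, gts)
  sweep <- confidence_sweep(preds, gts, conf_thresholds)
  best <- sweep[attr(sweep, "best"), , drop = FALSE]
  structure(list(per_class = per_class, map50 = maps$map50,
                 map50_95 = maps$map50_95, per_threshold = maps$per_threshold,
                 sweep = sweep, best_operating_point = best,
                 n_pred = nrow(preds), n_gt = nrow(gts)),
            class = "rgbdet_eval")
}

#' @export
print.rgbdet_eval <- function(x, ...) {
  cat("<rgbdet_eval>\n")
  cat(sprintf("  %d predictions vs %d ground truths\n", x$n_pred, x$n_gt))
  cat(sprintf("  mAP50 %.4f   mAP50:95 %.4f\n", x$map50, x$map50_95))
  b <- x$best_operating_point
  cat(sprintf("  best F1 %.4f at confidence %.2f (P %.4f, R %.4f)\n",
              b$f1, b$threshold, b$precision, b$recall))
  invisible(x)
}

#' Tidy method for evaluation reports: per-class, per-threshold rows
#' @param x an `rgbdet_eval`.
#' @param ... unused.
#' @export
tidy.rgbdet_eval <- function(x, ...) x$per_class

#' Glance method for evaluation reports: one-row summary
#' @param x an `rgbdet_eval`.
#' @param ... unused.
#' @export
glance.rgbdet_eval <- function(x, ...) {
  b <- x$best_operating_point
  tibble::tibble(map50 = x$map50, map50_95 = x$map50_95,
                 best_f1 = b$f1, best_conf = b$threshold,
                 precision = b$precision, recall = b$recall,
                 n_pred = x$n_pred, n_gt = x$n_gt)
}
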