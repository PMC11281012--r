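# Evaluation suite: hand-computed IoU/precision/recall fixtures, AP edge
# cases, the IoU ladder, and sweep monotonicity.

gt_box <- function(x1, y1, x2, y2, cls = 0L, image = 1L)
  tibble::tibble(image = image, x_min = x1, y_min = y1, x_max = x2, y_max = y2,
                 class_id = cls)

pred_box <- function(x1, y1, x2, y2, conf, cls = 0L, image = 1L)
  tibble::tibble(image = image, x_min = x1, y_min = y1, x_max = x2, y_max = y2,
                 class_id = cls, confidence = conf)

test_that("box IoU follows the hand geometry", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  expect_error(box_iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), "degenerate")
})

test_that("greedy matching handles the canonical cases", {
  gts <- dplyr::bind_rows(gt_box(0, 0, 10, 10), gt_box(20, 20, 30, 30))
  perfect <- jitter_preds(gts, conf = c(0.9, 0.8), shift = 0)
  mt <- match_detections(perfect, gts, 0.5)
  expect_identical(c(mt$tp, mt$fp, mt$fn), c(2L, 0L, 0L))
  none <- match_detections(perfect[0, ], gts, 0.5)
  expect_identical(c(none$tp, none$fp, none$fn), c(0L, 0L, 2L))
  # two predictions on one gt: higher-confidence one wins, other is FP
  gt1 <- gt_box(0, 0, 10, 10)
  two <- dplyr::bind_rows(pred_box(0, 0, 10, 9, 0.9),    # IoU 0.9
                          pred_box(0, 0, 10, 8, 0.8))    # IoU 0.8
  mt <- match_detections(two, gt1, 0.5)
  expect_identical(c(mt$tp, mt$fp, mt$fn), c(1L, 1L, 0L))
  expect_identical(mt$flags$tp, c(TRUE, FALSE))
  # strict threshold: IoU exactly at the threshold is not a match
  at_thr <- pred_box(0, 0, 10, 5, 0.9)                   # IoU exactly 0.5
  expect_identical(match_detections(at_thr, gt1, 0.5)$tp, 0L)
})

test_that("TP + FN equals the ground-truth count for random instances", {
  set.seed(41)
  for (i in 1:20) {
    ng <- sample(0:5, 1)
    gts <- if (ng > 0) dplyr::bind_rows(lapply(seq_len(ng), function(j) {
      x <- runif(1, 0, 80); y <- runif(1, 0, 80)
      gt_box(x, y, x + runif(1, 5, 20), y + runif(1, 5, 20),
             cls = sample(0:1, 1))
    })) else gt_box(0, 0, 1, 1)[0, ]
    np <- sample(0:5, 1)
    preds <- if (np > 0) dplyr::bind_rows(lapply(seq_len(np), function(j) {
      x <- runif(1, 0, 80); y <- runif(1, 0, 80)
      pred_box(x, y, x + runif(1, 5, 20), y + runif(1, 5, 20),
               runif(1), cls = sample(0:1, 1))
    })) else jitter_preds(gts)[0, ]
    for (thr in c(0.3, 0.5, 0.7)) {
      mt <- match_detections(preds, gts, thr)
      expect_identical(mt$tp + mt$fn, nrow(gts))
      expect_identical(mt$tp + mt$fp, nrow(preds))
    }
  }
})

test_that("precision and recall use the zero-denominator convention", {
  expect_equal(precision(9, 1), 0.9)
  expect_equal(recall(8, 2), 0.8)
  expect_equal(precision(0, 0), 0)
  expect_equal(recall(0, 0), 0)
})

test_that("average precision spans its closed-form edge cases", {
  gts <- dplyr::bind_rows(gt_box(0, 0, 10, 10), gt_box(20, 20, 30, 30),
                          gt_box(40, 40, 55, 55))
  perfect <- jitter_preds(gts, conf = c(0.9, 0.8, 0.7), shift = 0)
  expect_equal(average_precision(perfect, gts, 0.5), 1)
  expect_equal(average_precision(perfect[0, ], gts, 0.5), 0)
  # ranking TP, FP, TP, TP over 3 gts: integrate the PR curve by hand
  ranked <- dplyr::bind_rows(
    pred_box(0, 0, 10, 10, 0.9),           # TP (gt 1)
    pred_box(60, 60, 70, 70, 0.8),         # FP
    pred_box(20, 20, 30, 30, 0.7),         # TP (gt 2)
    pred_box(40, 40, 55, 55, 0.6))         # TP (gt 3)
  # prefix (tp, fp): (1,0) (1,1) (2,1) (3,1); all-point interpolation:
  # envelope precision at recall 1/3 is 1, at 2/3 and 1 it is 3/4
  expected <- (1 / 3) * 1 + (1 / 3) * (3 / 4) + (1 / 3) * (3 / 4)
  expect_equal(average_precision(ranked, gts, 0.5), expected)
  # the literal accuracy-style formula with TN = 0
  expect_equal(average_precision(ranked, gts, 0.5, method = "accuracy"),
               3 / 4)
})

test_that("mean AP averages classes and needs at least one", {
  expect_equal(mean_ap(c(a = 1, b = 1)), 1)
  expect_equal(mean_ap(c(a = 0.4, b = 0.6)), 0.5)
  expect_error(mean_ap(numeric()), "at least one")
})

test_that("the IoU ladder has exactly ten rungs and perfect predictions ace
           all of them", {
  gts <- dplyr::bind_rows(gt_box(0, 0, 10, 10, cls = 0),
                          gt_box(20, 20, 34, 34, cls = 1))
  perfect <- jitter_preds(gts, conf = c(1, 1), shift = 0)
  m <- map50_95(perfect, gts)
  expect_identical(nrow(m$per_threshold), 10L)
  expect_equal(m$per_threshold$iou_thr, seq(0.5, 0.95, by = 0.05))
  expect_equal(m$map50, 1)
  expect_equal(m$map50_95, 1)
  expect_equal(m$map50_95, mean(m$per_threshold$map))
})

test_that("confidence sweep retains all at 0, none above 1, and recall is
           monotone non-increasing", {
  set.seed(42)
  gts <- dplyr::bind_rows(gt_box(0, 0, 10, 10), gt_box(30, 30, 45, 45))
  preds <- dplyr::bind_rows(jitter_preds(gts, conf = c(0.9, 0.4)),
                            pred_box(60, 60, 70, 70, 0.2))
  sw <- confidence_sweep(preds, gts, thresholds = seq(0, 1, by = 0.1))
  expect_identical(sw$tp[1] + sw$fp[1], nrow(preds))
  high <- confidence_sweep(preds, gts, thresholds = 1 + 1e-9)
  expect_equal(high$recall, 0)
  expect_true(all(diff(sw$recall) <= 1e-12))
  # exhaustive filtering oracle at each threshold
  for (r in seq_len(nrow(sw))) {
    keep <- preds[preds$confidence >= sw$threshold[r], , drop = FALSE]
    mt <- match_detections(keep, gts, 0.5)
    expect_identical(sw$tp[r], mt$tp)
    expect_identical(sw$fn[r], mt$fn)
  }
})

test_that("eval reports are internally consistent and tidy/glance work", {
  set.seed(43)
  gts <- dplyr::bind_rows(gt_box(0, 0, 12, 12, cls = 0),
                          gt_box(30, 30, 46, 46, cls = 1),
                          gt_box(60, 5, 74, 21, cls = 0))
  preds <- dplyr::bind_rows(jitter_preds(gts, conf = c(0.95, 0.9, 0.85)),
                            pred_box(80, 80, 90, 90, 0.3, cls = 1))
  rep <- eval_detections(preds, gts)
  expect_equal(rep$map50_95, mean(rep$per_threshold$map))
  expect_true(all(rep$per_class$ap >= 0 & rep$per_class$ap <= 1))
  td <- tidy(rep)
  expect_identical(nrow(td), 2L * 10L)      # two classes, ten thresholds
  gl <- glance(rep)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("map50", "map50_95", "best_f1") %in% names(gl)))
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(autoplot(rep$sweep), "ggplot")
})
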