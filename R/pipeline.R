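# Pipeline entry points: generate | train | eval | predict. Thin wrappers
# over the generator, trainer, and evaluator, with config files and seeds;
# inst/cli/rgbdet.R exposes them as shell subcommands.

load_split_pairs <- function(data_dir, split = "train") {
  lab_dir <- file.path(data_dir, "labels", split)
  img_dir <- file.path(data_dir, "images", split)
  stems <- sub("\\.txt$", "", list.files(lab_dir, pattern = "\\.txt$"))
  if (length(stems) == 0L) stopf("no labelled scenes under %s", lab_dir)
  lapply(stems, function(stem) {
    ir <- file.path(img_dir, paste0(stem, "_ir.png"))
    load_pair(file.path(img_dir, paste0(stem, "_rgb.png")),
              file.path(img_dir, paste0(stem, "_depth.png")),
              file.path(lab_dir, paste0(stem, ".txt")),
              if (file.exists(ir)) ir else NULL)
  })
}

#' Generate a synthetic dataset (pipeline command)
#'
#' @param out_dir output directory.
#' @param n number of scenes.
#' @param config a [scene_config()].
#' @return the dataset manifest, invisibly.
#' @export
cmd_generate <- function(out_dir, n = 100L, config = scene_config()) {
  manifest <- generate_dataset(n, config, out_dir)
  message(sprintf("wrote %d scenes (%s) under %s", n,
                  paste(sprintf("%s=%d", names(split_counts(n)),
                                split_counts(n)), collapse = ", "),
                  out_dir))
  invisible(manifest)
}

#' Train a model on a generated or real dataset (pipeline command)
#'
#' @param data_dir dataset directory (images/ + labels/ + manifest).
#' @param out_dir run output directory (checkpoint + log).
#' @param model_cfg a [model_config()].
#' @param run_cfg an [run_config()].
#' @param verbose per-epoch progress lines.
#' @return list with `checkpoint` path, `log` tibble, and the `model`.
#' @export
cmd_train <- function(data_dir, out_dir, model_cfg = model_config(),
                      run_cfg = run_config(), verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- load_split_pairs(data_dir, "train")
  model <- build_model(model_cfg, seed = run_cfg$seed)
  fit <- train_model(model, pairs, run_cfg, verbose = verbose)
  ck <- file.path(out_dir, "model.ckpt")
  save_checkpoint(fit$model, ck)
  utils::write.csv(as.data.frame(fit$log)[
    c("epoch", "loss", "loss_obj", "loss_cls", "loss_box", "lr", "mosaic")],
    file.path(out_dir, "train_log.csv"), row.names = FALSE)
  list(checkpoint = ck, log = fit$log, model = fit$model)
}

#' Evaluate a checkpoint on a dataset split (pipeline command)
#'
#' @param checkpoint checkpoint path from [cmd_train()].
#' @param data_dir dataset directory.
#' @param split `"test"`, `"val"`, or `"train"`.
#' @param conf_thr,nms_iou prediction thresholds.
#' @param report_path optional JSON report output path.
#' @return an `rgbdet_eval` report.
#' @export
cmd_eval <- function(checkpoint, data_dir, split = "test", conf_thr = 0.05,
                     nms_iou = 0.5, report_path = NULL) {
  model <- load_checkpoint(checkpoint)
  pairs <- load_split_pairs(data_dir, split)
  ncls <- max(vapply(pairs, function(p)
    if (nrow(p$labels)) max(p$labels$class_id) + 1L else 0L, integer(1)))
  if (ncls > model$config$num_classes)
    stopf("dataset has %d classes but the checkpoint was trained with %d",
          ncls, model$config$num_classes)
  rep <- evaluate_pairs(model, pairs, conf_thr, nms_iou)
  if (!is.null(report_path)) {
    jsonlite::write_json(list(
      map50 = rep$map50, map50_95 = rep$map50_95,
      per_threshold = rep$per_threshold,
      best_operating_point = rep$best_operating_point,
      per_class = rep$per_class), report_path, auto_unbox = TRUE, digits = NA)
  }
  rep
}

#' Detect objects in one image pair with a checkpoint (pipeline command)
#'
#' @param checkpoint checkpoint path.
#' @param rgb_path,depth_path aligned input rasters.
#' @param ir_path optional IR raster.
#' @param conf_thr,nms_iou thresholds.
#' @return box tibble.
#' @export
cmd_predict <- function(checkpoint, rgb_path, depth_path, ir_path = NULL,
                        conf_thr = 0.25, nms_iou = 0.5) {
  model <- load_checkpoint(checkpoint)
  pair <- load_pair(rgb_path, depth_path, NULL, ir_path)
  predict_pair(model, pair, conf_thr, nms_iou)
}
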