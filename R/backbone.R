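# Dual-stream (optionally tri-stream) detection scaffold.
#
# Each modality has its own stage stack (stem at stride 4, then three stages
# at strides 8/16/32). An LGEM block can enhance the streams at every stage
# and an RFAM block fuses each stage's outputs (falling back to channel
# concatenation + 1x1 projection when disabled). The fused pyramid passes an
# SPP-style pooling block and a top-down merge neck, then per-scale heads
# emit (4 box, 1 objectness, num_classes) channels per cell. An optional
# RGB-fed auxiliary stream (pass-through "silence" input, CBLinear splits of
# the deepest fused feature, CBFuse merges) provides extra supervision during
# training and is skipped at inference.

#' Model configuration
#'
#' @param stage_channels integer vector of three per-stage channel widths,
#'   strictly increasing (channels expand as resolution shrinks).
#' @param stage_depth residual blocks per stage.
#' @param num_classes number of object classes.
#' @param input_size `(h, w)` input pixels, each divisible by 32 (the total
#'   stride).
#' @param modalities 2 (RGB + depth) or 3 (RGB + depth + IR).
#' @param scale channel-width preset: `"s"` (x0.25), `"m"` (x0.5), `"l"` (x1).
#' @param use_lgem,use_rfam,use_aux enable the enhancement block, the fusion
#'   block, and the auxiliary stream.
#' @return a `rgbdet_config` list.
#' @export
model_config <- function(stage_channels = c(16L, 32L, 64L), stage_depth = 1L,
                         num_classes = 4L, input_size = c(640L, 640L),
                         modalities = 2L, scale = c("l", "m", "s"),
                         use_lgem = TRUE, use_rfam = TRUE, use_aux = FALSE) {
  scale <- match.arg(scale)
  mult <- c(s = 0.25, m = 0.5, l = 1)[[scale]]
  if (length(stage_channels) != 3L)
    stopf("stage_channels must have length 3 (strides 8/16/32)")
  if (any(diff(stage_channels) <= 0))
    stopf("stage_channels must be strictly increasing, got %s",
          paste(stage_channels, collapse = ", "))
  if (num_classes < 1L) stopf("num_classes must be >= 1")
  if (any(input_size %% 32L != 0L))
    stopf("input dims must be divisible by the total stride 32, got %s",
          paste(input_size, collapse = "x"))
  if (!modalities %in% c(2L, 3L)) stopf("modalities must be 2 or 3")
  ch <- pmax(2L, 2L * as.integer(round(stage_channels * mult / 2)))
  for (i in seq_along(ch)[-1]) while (ch[i] <= ch[i - 1]) ch[i] <- ch[i] + 2L
  structure(list(stage_channels = ch, stage_depth = as.integer(stage_depth),
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 modalities = as.integer(modalities), scale = scale,
                 use_lgem = isTRUE(use_lgem), use_rfam = isTRUE(use_rfam),
                 use_aux = isTRUE(use_aux), strides = c(8L, 16L, 32L)),
            class = "rgbdet_config")
}

#' @export
print.rgbdet_config <- function(x, ...) {
  cat("<rgbdet_config>\n")
  cat(sprintf("  stages %s (strides 8/16/32), depth %d, scale %s\n",
              paste(x$stage_channels, collapse = "/"), x$stage_depth, x$scale))
  cat(sprintf("  %d modalities, %d classes, input %dx%d\n", x$modalities,
              x$num_classes, x$input_size[1], x$input_size[2]))
  cat(sprintf("  lgem %s, rfam %s, aux %s\n", x$use_lgem, x$use_rfam, x$use_aux))
  invisible(x)
}

res_block_init <- function(c) {
  list(conv1 = init_conv(c, c, 3L), conv2 = init_conv(c, c, 3L))
}

res_block_fwd <- function(x, w) {
  y <- ag_relu(ag_conv2d(x, w$conv1$W, w$conv1$b))
  y <- ag_conv2d(y, w$conv2$W, w$conv2$b)
  ag_relu(ag_add(x, y))
}

stream_init <- function(in_ch, cfg) {
  ch <- cfg$stage_channels
  stem_c <- max(2L, ch[1] %/% 2L)
  stages <- lapply(seq_len(3L), function(i) {
    prev <- if (i == 1L) stem_c else ch[i - 1L]
    list(down = init_conv(ch[i], prev, 3L),
         blocks = lapply(seq_len(cfg$stage_depth), function(j) res_block_init(ch[i])),
         ln = init_ln(ch[i]))   # keeps stream magnitudes bounded stage-to-stage
  })
  list(stem1 = init_conv(stem_c, in_ch, 3L),
       stem2 = init_conv(stem_c, stem_c, 3L),
       stages = stages)
}

stream_stem_fwd <- function(x, w) {
  x <- ag_relu(ag_conv2d(x, w$stem1$W, w$stem1$b, stride = 2L))
  ag_relu(ag_conv2d(x, w$stem2$W, w$stem2$b, stride = 2L))
}

stream_stage_fwd <- function(x, stage_w) {
  x <- ag_relu(ag_conv2d(x, stage_w$down$W, stage_w$down$b, stride = 2L))
  for (bw in stage_w$blocks) x <- res_block_fwd(x, bw)
  ag_layernorm(x, stage_w$ln$gamma, stage_w$ln$beta)
}

#' Build a detection model from a configuration
#'
#' Constructs weight-independent per-modality stage stacks of identical
#' topology, one LGEM and one RFAM per stage when enabled (concatenation +
#' 1x1 projection otherwise), an SPP-style + top-down neck, per-scale
#' detection heads, and the optional auxiliary stream. Initialisation is
#' fully seeded: identical config + seed gives identical weights.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialisation.
#' @return an `rgbdet_model` list of parameter leaves plus the config.
#' @export
build_model <- function(config, seed = 0L) {
  if (!inherits(config, "rgbdet_config")) stopf("config must be a model_config()")
  ch <- config$stage_channels
  nm <- config$modalities
  with_seed(derive_seed(seed, 7L), {
    streams <- list(rgb = stream_init(3L, config),
                    depth = stream_init(1L, config))
    if (nm == 3L) streams$ir <- stream_init(1L, config)
    lgem <- if (config$use_lgem)
      lapply(ch, function(c) lgem_init(c, modalities = nm)) else NULL
    if (config$use_rfam) {
      rfam <- lapply(ch, function(c)
        if (nm == 3L) rfam_tri_init(c) else rfam_init(c))
      proj <- NULL
    } else {
      rfam <- NULL
      proj <- lapply(ch, function(c) init_conv(c, nm * c, 1L))
    }
    neck <- list(
      spp = init_conv(ch[3], 3L * ch[3], 1L),
      lat3 = init_conv(ch[2], ch[3], 1L),
      merge2 = init_conv(ch[2], 2L * ch[2], 3L),
      lat2 = init_conv(ch[1], ch[2], 1L),
      merge1 = init_conv(ch[1], 2L * ch[1], 3L),
      ln3 = init_ln(ch[3]), ln2 = init_ln(ch[2]), ln1 = init_ln(ch[1])
    )
    out_ch <- 5L + config$num_classes
    head <- lapply(ch, function(c)
      list(conv = init_conv(c, c, 3L), pred = init_conv(out_ch, c, 1L)))
    # objectness prior: start predictions sparse
    for (h in head) h$pred$b$value[5] <- -2
    aux <- NULL
    if (config$use_aux) {
      aux <- list(
        stream = stream_init(3L, config),
        cblinear = init_conv(sum(ch), ch[3], 1L),
        cbfuse = lapply(ch, function(c) init_conv(c, 2L * c, 3L)),
        head = lapply(ch, function(c)
          list(conv = init_conv(c, c, 3L), pred = init_conv(out_ch, c, 1L)))
      )
    }
    structure(list(config = config, streams = streams, lgem = lgem,
                   rfam = rfam, proj = proj, neck = neck, head = head,
                   aux = aux, seed = as.integer(seed)),
              class = "rgbdet_model")
  })
}

#' @export
print.rgbdet_model <- function(x, ...) {
  cat("<rgbdet_model>", count_params(x), "parameters\n")
  print(x$config)
  invisible(x)
}

head_fwd <- function(x, hw) {
  y <- ag_relu(ag_conv2d(x, hw$conv$W, hw$conv$b))
  ag_conv2d(y, hw$pred$W, hw$pred$b)
}

upsample_to <- function(x, times) {
  for (i in seq_len(times)) x <- ag_upsample2(x)
  x
}

# Core forward; inputs are nodes or arrays, returns prediction nodes.
forward_core <- function(model, rgb, depth, ir = NULL, train = FALSE) {
  cfg <- model$config
  nm <- cfg$modalities
  feats <- list(as_node(ag_value(rgb)), as_node(ag_value(depth)))
  if (nm == 3L) {
    if (is.null(ir)) stopf("tri-modal model needs an ir input")
    feats[[3]] <- as_node(ag_value(ir))
  }
  sw <- model$streams
  for (m in seq_len(nm)) feats[[m]] <- stream_stem_fwd(feats[[m]], sw[[m]])
  fused <- vector("list", 3L)
  for (i in seq_len(3L)) {
    for (m in seq_len(nm))
      feats[[m]] <- stream_stage_fwd(feats[[m]], sw[[m]]$stages[[i]])
    if (cfg$use_lgem)
      feats <- lgem_forward_core(feats, model$lgem[[i]])
    if (cfg$use_rfam) {
      fused[[i]] <- if (nm == 3L) {
        w <- model$rfam[[i]]
        g1 <- rfam_forward_core(feats[[1]], feats[[2]], w$inner_xy)
        g2 <- rfam_forward_core(feats[[1]], feats[[3]], w$inner_xz)
        rfam_forward_core(g1, g2, w$outer)
      } else {
        rfam_forward_core(feats[[1]], feats[[2]], model$rfam[[i]])
      }
    } else {
      cat_f <- ag_concat_c(feats)
      fused[[i]] <- ag_conv2d(cat_f, model$proj[[i]]$W, model$proj[[i]]$b)
    }
  }
  nk <- model$neck
  spp_in <- ag_concat_c(list(fused[[3]], ag_maxpool2d(fused[[3]], 3L),
                             ag_maxpool2d(fused[[3]], 5L)))
  p3 <- ag_layernorm(ag_relu(ag_conv2d(spp_in, nk$spp$W, nk$spp$b)),
                     nk$ln3$gamma, nk$ln3$beta)
  u3 <- ag_upsample2(ag_conv2d(p3, nk$lat3$W, nk$lat3$b))
  p2 <- ag_layernorm(ag_relu(ag_conv2d(ag_concat_c(list(fused[[2]], u3)),
                                       nk$merge2$W, nk$merge2$b)),
                     nk$ln2$gamma, nk$ln2$beta)
  u2 <- ag_upsample2(ag_conv2d(p2, nk$lat2$W, nk$lat2$b))
  p1 <- ag_layernorm(ag_relu(ag_conv2d(ag_concat_c(list(fused[[1]], u2)),
                                       nk$merge1$W, nk$merge1$b)),
                     nk$ln1$gamma, nk$ln1$beta)
  preds <- list(head_fwd(p1, model$head[[1]]),
                head_fwd(p2, model$head[[2]]),
                head_fwd(p3, model$head[[3]]))
  aux_preds <- NULL
  if (train && cfg$use_aux) {
    ax <- model$aux
    silence <- as_node(ag_value(rgb))           # pass-through placeholder
    a <- stream_stem_fwd(silence, ax$stream)
    ch <- cfg$stage_channels
    splits <- ag_conv2d(fused[[3]], ax$cblinear$W, ax$cblinear$b)
    at <- 0L
    aux_preds <- vector("list", 3L)
    for (i in seq_len(3L)) {
      a <- stream_stage_fwd(a, ax$stream$stages[[i]])
      part <- ag_slice_c(splits, at + 1L, ch[i])
      at <- at + ch[i]
      part <- upsample_to(part, 3L - i)
      a <- ag_relu(ag_conv2d(ag_concat_c(list(a, part)),
                             ax$cbfuse[[i]]$W, ax$cbfuse[[i]]$b))
      aux_preds[[i]] <- head_fwd(a, ax$head[[i]])
    }
  }
  list(preds = preds, aux = aux_preds)
}

#' Run the detection forward pass
#'
#' @param model an `rgbdet_model`.
#' @param rgb array `(b, 3, h, w)`; `depth` array `(b, 1, h, w)`; optional
#'   `ir` array `(b, 1, h, w)` for tri-modal models.
#' @param depth,ir see `rgb`.
#' @return list of three per-scale prediction arrays
#'   `(b, 5 + num_classes, h/s, w/s)` for strides `s = 8, 16, 32`; channel
#'   order is (box tx, ty, tw, th, objectness, class logits).
#' @export
forward_model <- function(model, rgb, depth, ir = NULL) {
  check_feature_grid(rgb, "rgb"); check_feature_grid(depth, "depth")
  if (!identical(dim(rgb)[c(1, 3, 4)], dim(depth)[c(1, 3, 4)]))
    stopf("rgb and depth must share batch and spatial size: %s vs %s",
          fmt_dim(rgb), fmt_dim(depth))
  out <- forward_core(model, rgb, depth, ir, train = FALSE)
  lapply(out$preds, ag_value)
}

model_weight_lists <- function(model) {
  w <- list(model$streams, model$neck, model$head)
  if (!is.null(model$lgem)) w <- c(w, list(model$lgem))
  if (!is.null(model$rfam)) w <- c(w, list(model$rfam))
  if (!is.null(model$proj)) w <- c(w, list(model$proj))
  if (!is.null(model$aux)) w <- c(w, list(model$aux))
  w
}

model_params <- function(model) collect_params(model_weight_lists(model))

#' Count model parameters with the conv/FC closed form
#'
#' Convolution layers contribute `(K * in + 1) * out` parameters (`K` =
#' kernel height x width, `+1` the bias); fully-connected layers `(in + 1) *
#' out`. Normalisation affine parameters are enumerated directly. The result
#' always equals exhaustive enumeration of weight and bias elements
#' ([count_params_direct()]).
#'
#' @param model an `rgbdet_model`, or any nested weight list.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  w <- if (inherits(model, "rgbdet_model")) model_weight_lists(model) else model
  total <- 0
  walk <- function(x) {
    if (inherits(x, "ag_node")) {
      total <<- total + length(x$value)   # norm affine terms, enumerated
    } else if (is.list(x)) {
      if (!is.null(x$W) && inherits(x$W, "ag_node") &&
          length(dim(x$W$value)) == 4L) {
        d <- dim(x$W$value)               # (out, in, kh, kw)
        K <- d[3] * d[4]
        total <<- total + (K * d[2] + 1) * d[1]
      } else if (!is.null(x$W) && inherits(x$W, "ag_node") &&
                 length(dim(x$W$value)) == 2L) {
        d <- dim(x$W$value)               # FC (out, in)
        total <<- total + (d[2] + 1) * d[1]
      } else {
        for (el in x) walk(el)
      }
    }
  }
  walk(w)
  as.integer(total)
}

#' Count model parameters by exhaustive enumeration
#' @param model an `rgbdet_model` or nested weight list.
#' @return integer count of all weight and bias elements.
#' @export
count_params_direct <- function(model) {
  w <- if (inherits(model, "rgbdet_model")) model_weight_lists(model) else model
  as.integer(n_param_values(w))
}

#' Wall-clock speed of the forward pass
#'
#' Milliseconds per sample over `n` repeated forward passes; a report-only
#' convenience, strongly hardware dependent.
#'
#' @param model an `rgbdet_model`.
#' @param pairs list of `list(rgb =, depth =, ir =)` input arrays.
#' @return milliseconds per sample (numeric).
#' @export
measure_speed <- function(model, pairs) {
  if (length(pairs) < 1L) stopf("need at least one sample")
  t0 <- proc.time()[["elapsed"]]
  for (p in pairs) forward_model(model, p$rgb, p$depth, p$ir)
  (proc.time()[["elapsed"]] - t0) * 1000 / length(pairs)
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single file holding the configuration, the seed, and
#' every named parameter array.
#'
#' @param model an `rgbdet_model`.
#' @param path file path.
#' @return `load_checkpoint()` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, seed = model$seed,
               state = params_state(model_weight_lists(model))), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config, seed = ck$seed)
  params_load(model_weight_lists(model), ck$state)
  model
}
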