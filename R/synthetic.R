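# Synthetic aligned RGB-D orchard scenes.
#
# Scenes contain ellipse "fruits" on a textured foliage background, with
# class-dependent occluders (leaf blobs, branch strokes, overlapping
# unlabelled fruit), a depth channel that encodes per-object distance (the
# painter's order), uncontrolled-lighting corruptions of the RGB channel
# only, and hollow depth noise: invalid (zero) depth pixels ringing each
# fruit boundary. Class ids: 0 = False (unshaded), 1 = Leaf, 2 = Branch,
# 3 = Fruit.

#' Scene generator configuration
#'
#' Defaults emulate the orchard imagery the detector targets: 640x640
#' frames, a handful of small, centre-biased fruits per scene, a leaf-heavy
#' occlusion mix, and moderate depth-void noise. The `"easy"` preset is the
#' benign end of the generator's range: larger unoccluded fruits under
#' normal lighting, used for desk-scale end-to-end training checks.
#'
#' @param image_size `(h, w)` pixels.
#' @param n_fruit_range inclusive integer range of fruits per scene.
#' @param class_mix probabilities over the four occlusion classes
#'   (False, Leaf, Branch, Fruit); must sum to 1.
#' @param lighting one of `"normal"`, `"dark"`, `"glare"`.
#' @param depth_void_rate probability in `[0, 1]` that a fruit-boundary
#'   depth pixel is carved to the invalid-depth sentinel 0.
#' @param fruit_radius_range fruit radius as a fraction of `min(image_size)`.
#' @param with_ir also synthesise a near-constant infrared raster.
#' @param seed integer; scenes are bit-reproducible given config + seed.
#' @param preset `"orchard"` (defaults above) or `"easy"`.
#' @return a `scene_config` list.
#' @export
scene_config <- function(image_size = c(640L, 640L),
                         n_fruit_range = c(2L, 6L),
                         class_mix = c(False = 0.2, Leaf = 0.5,
                                       Branch = 0.15, Fruit = 0.15),
                         lighting = c("normal", "dark", "glare"),
                         depth_void_rate = 0.3,
                         fruit_radius_range = c(0.035, 0.065),
                         with_ir = FALSE, seed = 0L,
                         preset = c("orchard", "easy")) {
  preset <- match.arg(preset)
  lighting <- match.arg(lighting)
  if (preset == "easy") {
    if (missing(image_size)) image_size <- c(128L, 128L)
    if (missing(n_fruit_range)) n_fruit_range <- c(1L, 2L)
    if (missing(class_mix))
      class_mix <- c(False = 1, Leaf = 0, Branch = 0, Fruit = 0)
    if (missing(depth_void_rate)) depth_void_rate <- 0.1
    if (missing(fruit_radius_range)) fruit_radius_range <- c(0.13, 0.2)
  }
  if (any(image_size < 8L)) stopf("image_size too small")
  if (abs(sum(class_mix) - 1) > 1e-8) stopf("class_mix must sum to 1")
  if (depth_void_rate < 0 || depth_void_rate > 1)
    stopf("depth_void_rate must lie in [0, 1]")
  if (n_fruit_range[1] > n_fruit_range[2] || n_fruit_range[1] < 0L)
    stopf("invalid n_fruit_range")
  structure(list(image_size = as.integer(image_size),
                 n_fruit_range = as.integer(n_fruit_range),
                 class_mix = class_mix, lighting = lighting,
                 depth_void_rate = depth_void_rate,
                 fruit_radius_range = fruit_radius_range,
                 with_ir = isTRUE(with_ir), seed = as.integer(seed),
                 preset = preset),
            class = "scene_config")
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# Paint an ellipse into the scene respecting depth order (smaller depth =
# nearer = wins). `scene` is an environment with rgb (h,w,3) and depth (h,w).
paint_ellipse <- function(scene, cx, cy, rx, ry, col, d, shade = 0.3) {
  h <- nrow(scene$depth); w <- ncol(scene$depth)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  Y <- matrix(seq_len(h), h, w)
  rr <- ((X - cx) / rx)^2 + ((Y - cy) / ry)^2
  mask <- rr <= 1 & d < scene$depth
  if (!any(mask)) return(invisible(scene))
  fade <- 1 - shade * rr[mask]
  for (ch in 1:3) {
    plane <- scene$rgb[, , ch]
    plane[mask] <- clamp01(col[ch] * fade)
    scene$rgb[, , ch] <- plane
  }
  scene$depth[mask] <- d
  invisible(scene)
}

paint_stroke <- function(scene, cx, cy, angle, len, thick, col, d) {
  h <- nrow(scene$depth); w <- ncol(scene$depth)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  Y <- matrix(seq_len(h), h, w)
  ux <- cos(angle); uy <- sin(angle)
  t <- (X - cx) * ux + (Y - cy) * uy          # along-stroke coordinate
  s <- -(X - cx) * uy + (Y - cy) * ux         # across-stroke
  mask <- abs(t) <= len / 2 & abs(s) <= thick / 2 & d < scene$depth
  if (!any(mask)) return(invisible(scene))
  for (ch in 1:3) {
    plane <- scene$rgb[, , ch]
    plane[mask] <- col[ch]
    scene$rgb[, , ch] <- plane
  }
  scene$depth[mask] <- d
  invisible(scene)
}

#' Generate one aligned synthetic RGB-D scene
#'
#' Deterministic given config + seed: the same configuration always renders
#' bit-identical rasters and labels.
#'
#' @param config a [scene_config()].
#' @return a `synthetic_scene`: list with `rgb` (h, w, 3 array in `[0, 1]`),
#'   `depth` (h, w matrix in `[0, 1]`, 0 = invalid sentinel), optional `ir`,
#'   `labels` (tibble class_id/xc/yc/w/h, normalised), and `config`.
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "scene_config")) stopf("config must be a scene_config()")
  h <- config$image_size[1]; w <- config$image_size[2]
  with_seed(derive_seed(config$seed, 11L), {
    scene <- new.env()
    base <- c(0.30, 0.44, 0.22)
    grad <- matrix(seq(0, 0.08, length.out = h), h, w)
    scene$rgb <- array(0, c(h, w, 3))
    for (ch in 1:3)
      scene$rgb[, , ch] <- clamp01(base[ch] + grad +
                                     matrix(rnorm(h * w, sd = 0.04), h, w))
    scene$depth <- matrix(clamp01(0.92 + rnorm(h * w, sd = 0.015)), h, w)

    n <- if (config$n_fruit_range[1] == config$n_fruit_range[2])
      config$n_fruit_range[1]
    else sample(config$n_fruit_range[1]:config$n_fruit_range[2], 1L)
    mind <- min(h, w)
    objs <- list()
    for (i in seq_len(n)) {
      rx <- runif(1, config$fruit_radius_range[1],
                  config$fruit_radius_range[2]) * mind
      ry <- rx * runif(1, 0.85, 1.15)
      cx <- min(w - rx - 1, max(rx + 1, w * (0.5 + rnorm(1, sd = 0.14))))
      cy <- min(h - ry - 1, max(ry + 1, h * (0.5 + rnorm(1, sd = 0.14))))
      cls <- sample(0:3, 1L, prob = config$class_mix)
      d <- runif(1, 0.35, 0.75)
      objs[[i]] <- list(cx = cx, cy = cy, rx = rx, ry = ry, cls = cls, d = d)
    }
    # painter's order: far first
    for (o in objs[order(vapply(objs, `[[`, numeric(1), "d"),
                         decreasing = TRUE)]) {
      col <- clamp01(c(0.93, 0.55, 0.35) + rnorm(3, sd = 0.05))
      paint_ellipse(scene, o$cx, o$cy, o$rx, o$ry, col, o$d)
      if (o$cls == 1L) {                      # leaf occluder
        for (k in seq_len(sample(1:2, 1L))) {
          ang <- runif(1, 0, 2 * pi)
          paint_ellipse(scene, o$cx + cos(ang) * o$rx, o$cy + sin(ang) * o$ry,
                        o$rx * runif(1, 0.4, 0.7), o$ry * runif(1, 0.4, 0.7),
                        c(0.13, 0.42, 0.16), o$d - 0.05)
        }
      } else if (o$cls == 2L) {               # branch stroke
        paint_stroke(scene, o$cx, o$cy, runif(1, 0, pi), 3.5 * o$rx,
                     0.45 * o$rx, c(0.32, 0.22, 0.12), o$d - 0.05)
      } else if (o$cls == 3L) {               # unlabelled occluding fruit
        ang <- runif(1, 0, 2 * pi)
        paint_ellipse(scene, o$cx + cos(ang) * 1.05 * o$rx,
                      o$cy + sin(ang) * 1.05 * o$ry,
                      o$rx * 0.8, o$ry * 0.8,
                      clamp01(c(0.9, 0.5, 0.33) + rnorm(3, sd = 0.04)),
                      o$d - 0.05)
      }
    }
    labels <- tibble::tibble(
      class_id = vapply(objs, function(o) as.integer(o$cls), integer(1)),
      xc = vapply(objs, function(o) o$cx / w, numeric(1)),
      yc = vapply(objs, function(o) o$cy / h, numeric(1)),
      w = vapply(objs, function(o) 2 * o$rx / w, numeric(1)),
      h = vapply(objs, function(o) 2 * o$ry / h, numeric(1)))

    rgb <- scene$rgb
    if (config$lighting != "normal")
      rgb <- corrupt_lighting(rgb, config$lighting,
                              seed = derive_seed(config$seed, 23L))
    depth <- carve_depth_voids(scene$depth, labels, config$depth_void_rate,
                               seed = derive_seed(config$seed, 31L))
    ir <- NULL
    if (config$with_ir)
      ir <- matrix(clamp01(0.5 + rnorm(h * w, sd = 0.01)), h, w)
    structure(list(rgb = rgb, depth = depth, ir = ir, labels = labels,
                   config = config),
              class = "synthetic_scene")
  })
}

#' Corrupt the lighting of an RGB raster
#'
#' `dark`: global gain below one plus pixel noise (artificial-light night
#' scenes); `glare`: a saturated bright disc overwriting local content (lens
#' facing the sun). Depth is never touched: the depth channel is robust to
#' lighting.
#'
#' @param rgb `(h, w, 3)` array in `[0, 1]`.
#' @param mode `"dark"` or `"glare"`.
#' @param seed integer seed.
#' @param gain dark-mode global gain (default 0.35).
#' @param noise_sd dark-mode additive noise sd.
#' @return corrupted `(h, w, 3)` array.
#' @export
corrupt_lighting <- function(rgb, mode, seed = 0L, gain = 0.35,
                             noise_sd = 0.03) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stopf("rgb must be an (h, w, 3) array")
  if (!mode %in% c("dark", "glare")) stopf("unknown lighting mode '%s'", mode)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  with_seed(derive_seed(seed, 41L), {
    if (mode == "dark") {
      if (gain == 1 && noise_sd == 0) return(rgb)
      out <- rgb * gain
      if (noise_sd > 0) out <- out + array(rnorm(length(out), sd = noise_sd),
                                           dim(out))
      clamp01(out)
    } else {
      cx <- runif(1, 0.2, 0.8) * w; cy <- runif(1, 0.2, 0.8) * h
      r <- runif(1, 0.1, 0.2) * min(h, w)
      X <- matrix(seq_len(w), h, w, byrow = TRUE)
      Y <- matrix(seq_len(h), h, w)
      mask <- (X - cx)^2 + (Y - cy)^2 <= r^2
      out <- rgb
      for (ch in 1:3) {
        plane <- out[, , ch]
        plane[mask] <- 1
        out[, , ch] <- plane
      }
      out
    }
  })
}

#' Carve hollow depth noise around fruit boundaries
#'
#' Sets pixels in an annulus around each labelled fruit's ellipse boundary
#' to the invalid-depth sentinel 0 with the given probability, emulating the
#' boundary voids of consumer depth sensors.
#'
#' @param depth `(h, w)` depth matrix.
#' @param labels tibble of normalised label records (class_id, xc, yc, w, h).
#' @param rate void probability in `[0, 1]`.
#' @param seed integer seed.
#' @return depth matrix with carved voids.
#' @export
carve_depth_voids <- function(depth, labels, rate, seed = 0L) {
  if (rate < 0 || rate > 1) stopf("rate must lie in [0, 1]")
  if (rate == 0 || is.null(labels) || nrow(labels) == 0L) return(depth)
  h <- nrow(depth); w <- ncol(depth)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  Y <- matrix(seq_len(h), h, w)
  with_seed(derive_seed(seed, 53L), {
    for (r in seq_len(nrow(labels))) {
      cx <- labels$xc[r] * w; cy <- labels$yc[r] * h
      rx <- labels$w[r] * w / 2; ry <- labels$h[r] * h / 2
      rr <- ((X - cx) / rx)^2 + ((Y - cy) / ry)^2
      ring <- rr >= 0.8 & rr <= 1.2
      if (!any(ring)) next
      hit <- if (rate >= 1) rep(TRUE, sum(ring))
             else runif(sum(ring)) < rate
      idx <- which(ring)[hit]
      depth[idx] <- 0
    }
    depth
  })
}

split_counts <- function(n) {
  nv <- n %/% 10L; nt <- n %/% 10L
  c(train = n - nv - nt, val = nv, test = nt)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` scenes as PNG image pairs plus YOLO-format label files into
#' `images/{split}/` and `labels/{split}/` under `dir`, split
#' train/val/test in the ratio 8:1:1, together with a JSON manifest holding
#' the configuration and every per-scene seed so the dataset can be
#' regenerated bit-exactly.
#'
#' @param n number of scenes (>= 10).
#' @param config a [scene_config()]; per-scene seeds are derived from
#'   `config$seed`.
#' @param dir output directory.
#' @return the manifest (invisibly), also written to `manifest.json`.
#' @export
generate_dataset <- function(n, config, dir) {
  if (n < 10L) stopf("need n >= 10 scenes for an 8:1:1 split, got %d", n)
  counts <- split_counts(n)
  splits <- rep(names(counts), counts)
  files <- character(n)
  seeds <- integer(n)
  for (sp in unique(splits)) {
    dir.create(file.path(dir, "images", sp), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "labels", sp), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(n)) {
    seeds[i] <- derive_seed(config$seed, 1000L + i)
    cfg_i <- config; cfg_i$seed <- seeds[i]
    scene <- generate_scene(cfg_i)
    stem <- sprintf("scene_%05d", i)
    files[i] <- stem
    write_scene(scene, dir, splits[i], stem)
  }
  manifest <- list(n = n, counts = as.list(counts),
                   config = unclass(config), scene_seeds = seeds,
                   splits = splits, files = files,
                   depth_sentinel = 0)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

write_scene <- function(scene, dir, split, stem) {
  png::writePNG(scene$rgb, file.path(dir, "images", split,
                                     paste0(stem, "_rgb.png")))
  png::writePNG(scene$depth, file.path(dir, "images", split,
                                       paste0(stem, "_depth.png")))
  if (!is.null(scene$ir))
    png::writePNG(scene$ir, file.path(dir, "images", split,
                                      paste0(stem, "_ir.png")))
  write_labels(scene$labels, file.path(dir, "labels", split,
                                       paste0(stem, ".txt")))
  invisible(NULL)
}

#' Regenerate a dataset from its manifest
#'
#' @param manifest_path path to a `manifest.json` from [generate_dataset()].
#' @param dir output directory.
#' @return the manifest, invisibly.
#' @export
regenerate_dataset <- function(manifest_path, dir) {
  mf <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- do.call(scene_config, c(
    mf$config[c("image_size", "n_fruit_range", "lighting", "depth_void_rate",
                "fruit_radius_range", "with_ir", "seed")],
    list(class_mix = unlist(mf$config$class_mix))))
  for (sp in unique(mf$splits)) {
    dir.create(file.path(dir, "images", sp), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "labels", sp), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(mf$n)) {
    cfg_i <- cfg; cfg_i$seed <- mf$scene_seeds[i]
    write_scene(generate_scene(cfg_i), dir, mf$splits[i], mf$files[i])
  }
  jsonlite::write_json(mf, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mf)
}
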