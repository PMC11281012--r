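# YOLO-format label IO, aligned image-pair loading, and the joint RGB-depth
# mosaic augmentation with its training schedule.

#' Read and write YOLO-format label files
#'
#' One object per whitespace-separated line: `class xc yc w h` with
#' normalised coordinates in `[0, 1]`. Round trips preserve values to six
#' decimals. A missing file reads as an empty label set.
#'
#' @param path label file path.
#' @return `read_labels()`: tibble with columns class_id, xc, yc, w, h.
#' @export
read_labels <- function(path) {
  empty <- tibble::tibble(class_id = integer(), xc = numeric(),
                          yc = numeric(), w = numeric(), h = numeric())
  if (!file.exists(path)) return(empty)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 5L)
      stopf("%s line %d: expected 5 fields, got %d", path, i, length(parts))
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals))
      stopf("%s line %d: non-numeric field", path, i)
    if (vals[1] < 0 || vals[1] != floor(vals[1]))
      stopf("%s line %d: class id must be a non-negative integer", path, i)
    if (any(vals[2:5] < 0) || any(vals[2:5] > 1))
      stopf("%s line %d: normalised coordinates must lie in [0, 1]", path, i)
    recs[[i]] <- vals
  }
  m <- do.call(rbind, recs)
  tibble::tibble(class_id = as.integer(m[, 1]), xc = m[, 2], yc = m[, 3],
                 w = m[, 4], h = m[, 5])
}

#' @rdname read_labels
#' @param labels tibble of label records.
#' @export
write_labels <- function(labels, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", labels$class_id, labels$xc,
                   labels$yc, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

#' Load an aligned RGB-depth image pair with its labels
#'
#' Decodes the rasters, asserts pixel alignment (identical spatial size),
#' and attaches the shared label set. A missing label file yields an empty
#' label set with a warning.
#'
#' @param rgb_path,depth_path PNG paths; `ir_path` optional.
#' @param label_path YOLO label file path.
#' @param ir_path optional IR raster path.
#' @return an `image_pair`: list with `rgb` (h, w, 3), `depth` (h, w),
#'   optional `ir`, `labels`, and source paths.
#' @export
load_pair <- function(rgb_path, depth_path, label_path = NULL, ir_path = NULL) {
  rgb <- png::readPNG(rgb_path)
  if (length(dim(rgb)) == 2L) rgb <- array(rep(rgb, 3), c(dim(rgb), 3L))
  if (dim(rgb)[3] > 3L) rgb <- rgb[, , 1:3, drop = FALSE]
  depth <- png::readPNG(depth_path)
  if (length(dim(depth)) == 3L) depth <- depth[, , 1]
  if (!identical(dim(rgb)[1:2], dim(depth)))
    stopf("rgb (%s) and depth (%s) are not aligned",
          paste(dim(rgb)[1:2], collapse = "x"),
          paste(dim(depth), collapse = "x"))
  ir <- NULL
  if (!is.null(ir_path)) {
    ir <- png::readPNG(ir_path)
    if (length(dim(ir)) == 3L) ir <- ir[, , 1]
    if (!identical(dim(ir), dim(depth)))
      stopf("ir raster is not aligned with the pair")
  }
  labels <- NULL
  if (!is.null(label_path)) {
    if (!file.exists(label_path)) {
      warning(sprintf("no label file at %s; using an empty label set",
                      label_path), call. = FALSE)
      labels <- read_labels(label_path)
    } else labels <- read_labels(label_path)
  } else {
    labels <- read_labels(tempfile())  # empty set
  }
  structure(list(rgb = rgb, depth = depth, ir = ir, labels = labels,
                 rgb_path = rgb_path, depth_path = depth_path),
            class = "image_pair")
}

# Bilinear resize of an (h, w) matrix or (h, w, c) array.
resize_bilinear <- function(img, oh, ow) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  ys <- (seq_len(oh) - 0.5) * h / oh + 0.5
  xs <- (seq_len(ow) - 0.5) * w / ow + 0.5
  y0 <- pmin(h, pmax(1, floor(ys))); y1 <- pmin(h, y0 + 1)
  x0 <- pmin(w, pmax(1, floor(xs))); x1 <- pmin(w, x0 + 1)
  fy <- pmin(1, pmax(0, ys - y0)); fx <- pmin(1, pmax(0, xs - x0))
  one_plane <- function(p) {
    a <- p[y0, x0, drop = FALSE] * (1 - fy) + p[y1, x0, drop = FALSE] * fy
    b <- p[y0, x1, drop = FALSE] * (1 - fy) + p[y1, x1, drop = FALSE] * fy
    a * matrix(1 - fx, oh, ow, byrow = TRUE) + b * matrix(fx, oh, ow, byrow = TRUE)
  }
  if (length(d) == 2L) return(one_plane(img))
  out <- array(0, c(oh, ow, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- one_plane(img[, , ch])
  out
}

# Nearest-neighbour resize (used for depth so no values are invented
# across object boundaries).
resize_nearest <- function(img, oh, ow) {
  d <- dim(img)
  yi <- pmin(d[1], pmax(1, ceiling((seq_len(oh) - 0.5) * d[1] / oh)))
  xi <- pmin(d[2], pmax(1, ceiling((seq_len(ow) - 0.5) * d[2] / ow)))
  if (length(d) == 2L) img[yi, xi, drop = FALSE] else img[yi, xi, , drop = FALSE]
}

#' Four-scene mosaic augmentation, applied jointly to RGB and depth
#'
#' Samples one mosaic centre (uniform within the central half of the
#' canvas), scales each of the four scenes into its quadrant with the
#' identical geometric transform for RGB, depth (and IR when present), and
#' re-normalises the label boxes with the same transform. Boxes whose
#' clipped area falls below 1% of their original are dropped. The output
#' pair remains strictly aligned.
#'
#' @param pairs list of exactly four `image_pair` objects.
#' @param out_size `(h, w)` canvas size in pixels.
#' @param seed integer seed for the centre draw.
#' @param center optional fixed mosaic centre `(y, x)` in pixels, overriding
#'   the random draw.
#' @return a mosaicked `image_pair`.
#' @export
mosaic4 <- function(pairs, out_size, seed = 0L, center = NULL) {
  if (length(pairs) != 4L) stopf("mosaic4 needs exactly 4 pairs, got %d",
                                 length(pairs))
  H <- out_size[1]; W <- out_size[2]
  if (is.null(center)) {
    with_seed(derive_seed(seed, 67L), {
      cy <- round(runif(1, 0.25, 0.75) * H)
      cx <- round(runif(1, 0.25, 0.75) * W)
    })
  } else {
    cy <- center[1]; cx <- center[2]
  }
  cy <- min(H - 1L, max(1L, cy)); cx <- min(W - 1L, max(1L, cx))
  has_ir <- !is.null(pairs[[1]]$ir)
  rgb <- array(0, c(H, W, 3))
  depth <- matrix(0, H, W)
  ir <- if (has_ir) matrix(0, H, W) else NULL
  quads <- list(list(ys = 1:cy, xs = 1:cx),
                list(ys = 1:cy, xs = (cx + 1):W),
                list(ys = (cy + 1):H, xs = 1:cx),
                list(ys = (cy + 1):H, xs = (cx + 1):W))
  labs <- list()
  for (i in 1:4) {
    p <- pairs[[i]]
    q <- quads[[i]]
    qh <- length(q$ys); qw <- length(q$xs)
    rgb[q$ys, q$xs, ] <- resize_bilinear(p$rgb, qh, qw)
    depth[q$ys, q$xs] <- resize_nearest(p$depth, qh, qw)
    if (has_ir) ir[q$ys, q$xs] <- resize_nearest(p$ir, qh, qw)
    lb <- p$labels
    if (!is.null(lb) && nrow(lb) > 0L) {
      ox <- q$xs[1] - 1L; oy <- q$ys[1] - 1L
      xc <- (ox + lb$xc * qw) / W
      yc <- (oy + lb$yc * qh) / H
      bw <- lb$w * qw / W
      bh <- lb$h * qh / H
      # clip to the unit square
      x1 <- pmax(0, xc - bw / 2); x2 <- pmin(1, xc + bw / 2)
      y1 <- pmax(0, yc - bh / 2); y2 <- pmin(1, yc + bh / 2)
      keep <- (x2 - x1) * (y2 - y1) > 0.01 * bw * bh
      if (any(keep))
        labs[[length(labs) + 1L]] <- tibble::tibble(
          class_id = lb$class_id[keep],
          xc = ((x1 + x2) / 2)[keep], yc = ((y1 + y2) / 2)[keep],
          w = (x2 - x1)[keep], h = (y2 - y1)[keep])
    }
  }
  labels <- if (length(labs)) dplyr::bind_rows(labs)
            else read_labels(tempfile())
  structure(list(rgb = rgb, depth = depth, ir = ir, labels = labels,
                 center = c(y = cy, x = cx)),
            class = "image_pair")
}

#' Mosaic training schedule
#'
#' Mosaic augmentation is active for every epoch except the final
#' `close_window` epochs (turned off near the end to sharpen convergence).
#' Epochs are zero-based.
#'
#' @param epoch zero-based epoch index, `0 <= epoch < total_epochs`.
#' @param total_epochs configured epoch count.
#' @param close_window number of final epochs with mosaic disabled
#'   (default 30).
#' @return `TRUE` when mosaic is active at `epoch`.
#' @export
mosaic_schedule <- function(epoch, total_epochs, close_window = 30L) {
  if (epoch < 0L || epoch >= total_epochs)
    stopf("epoch must satisfy 0 <= epoch < total_epochs")
  epoch < total_epochs - close_window
}
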