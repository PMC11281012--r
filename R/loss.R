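# Anchor-free detection loss.
#
# Per-cell raw channels are (tx, ty, tw, th, objectness, class logits) with
# the bounded decode px = (2 sig(tx) - 0.5 + cx) * stride and
# pw = (2 sig(tw))^2 * base, base = 4 x stride, so a zero raw size predicts
# the scale's base box. A ground truth is positive at every pyramid scale,
# in each cell whose centre falls inside the box and within 1.5 strides of
# the box centre (provided the offset stays decodable); this puts box
# supervision on the whole cluster of cells that will respond to the
# object, so NMS sees a consistent cloud. The loss is objectness BCE
# (positive and negative halves balanced), class BCE on positive cells, and
# an IoU-based box term (1 - IoU plus a scaled centre-distance penalty, so
# disjoint boxes still receive a gradient).

BOX_SIZE_MULT <- 4
CENTER_PEN <- 0.2

# labels: tibble (class_id, xc, yc, w, h) normalised; returns per-scale
# assignment tables and dense objectness/class targets.
assign_targets <- function(labels_list, input_size, num_classes,
                           strides = c(8L, 16L, 32L)) {
  H <- input_size[1]; W <- input_size[2]
  B <- length(labels_list)
  per_scale <- lapply(strides, function(s) {
    gh <- H %/% s; gw <- W %/% s
    list(stride = s, gh = gh, gw = gw,
         t_obj = array(0, c(B, 1L, gh, gw)),
         t_cls = array(0, c(B, num_classes, gh, gw)),
         pos = list())
  })
  for (b in seq_len(B)) {
    lb <- labels_list[[b]]
    if (is.null(lb) || nrow(lb) == 0L) next
    for (r in seq_len(nrow(lb))) {
      gx <- lb$xc[r] * W; gy <- lb$yc[r] * H
      bw <- lb$w[r] * W; bh <- lb$h[r] * H
      for (k in seq_along(strides)) {
        s <- strides[k]
        base <- BOX_SIZE_MULT * s
        # size must be reachable through (2 sig)^2 * base
        if (bw >= 3.9 * base || bh >= 3.9 * base ||
            bw <= 0.02 * base || bh <= 0.02 * base) next
        gh_k <- per_scale[[k]]$gh; gw_k <- per_scale[[k]]$gw
        ci <- 1L + floor(gy / s); cj <- 1L + floor(gx / s)
        for (gi in max(1L, ci - 2L):min(gh_k, ci + 2L))
          for (gj in max(1L, cj - 2L):min(gw_k, cj + 2L)) {
            ccx <- (gj - 0.5) * s; ccy <- (gi - 0.5) * s
            inside <- abs(ccx - gx) <= bw / 2 && abs(ccy - gy) <= bh / 2
            near <- abs(ccx - gx) <= 1.5 * s && abs(ccy - gy) <= 1.5 * s
            ox <- gx / s - (gj - 1L); oy <- gy / s - (gi - 1L)
            feasible <- ox > -0.45 && ox < 1.45 && oy > -0.45 && oy < 1.45
            if (!(inside && near && feasible)) next
            if (per_scale[[k]]$t_obj[b, 1L, gi, gj] == 1) next  # first gt wins
            per_scale[[k]]$t_obj[b, 1L, gi, gj] <- 1
            cls <- lb$class_id[r] + 1L
            if (cls >= 1L && cls <= num_classes)
              per_scale[[k]]$t_cls[b, cls, gi, gj] <- 1
            per_scale[[k]]$pos[[length(per_scale[[k]]$pos) + 1L]] <-
              c(b = b, gi = gi, gj = gj, x = gx, y = gy, w = bw, h = bh)
          }
      }
    }
  }
  lapply(per_scale, function(ps) {
    ps$pos <- if (length(ps$pos)) as.data.frame(do.call(rbind, ps$pos))
              else NULL
    ps
  })
}

sigm <- function(z) 1 / (1 + exp(-z))

# Custom autograd op: IoU-based box loss for the positive cells of one
# scale. `box` is the (B, 4, gh, gw) node of raw tx/ty/tw/th maps.
ag_box_iou_loss <- function(box, pos, stride) {
  box <- as_node(box)
  if (is.null(pos) || nrow(pos) == 0L)
    return(ag_node(array(0, 1L), list(box),
                   function(g) list(array(0, dim(box$value)))))
  bv <- box$value
  n <- nrow(pos)
  base <- BOX_SIZE_MULT * stride
  per <- vector("list", n)
  total <- 0
  for (r in seq_len(n)) {
    b <- pos$b[r]; gi <- pos$gi[r]; gj <- pos$gj[r]
    tx <- bv[b, 1, gi, gj]; ty <- bv[b, 2, gi, gj]
    tw <- bv[b, 3, gi, gj]; th <- bv[b, 4, gi, gj]
    sx <- sigm(tx); sy <- sigm(ty)
    sw <- sigm(tw); sh <- sigm(th)
    px <- (2 * sx - 0.5 + gj - 1) * stride
    py <- (2 * sy - 0.5 + gi - 1) * stride
    pw <- (2 * sw)^2 * base;     ph <- (2 * sh)^2 * base
    x1p <- px - pw / 2; x2p <- px + pw / 2
    y1p <- py - ph / 2; y2p <- py + ph / 2
    x1g <- pos$x[r] - pos$w[r] / 2; x2g <- pos$x[r] + pos$w[r] / 2
    y1g <- pos$y[r] - pos$h[r] / 2; y2g <- pos$y[r] + pos$h[r] / 2
    iw <- max(0, min(x2p, x2g) - max(x1p, x1g))
    ih <- max(0, min(y2p, y2g) - max(y1p, y1g))
    I <- iw * ih
    Ap <- pw * ph; Ag <- pos$w[r] * pos$h[r]
    U <- Ap + Ag - I
    iou <- I / U
    cen <- ((px - pos$x[r])^2 + (py - pos$y[r])^2) / base^2
    total <- total + (1 - iou) + CENTER_PEN * cen
    per[[r]] <- list(b = b, gi = gi, gj = gj, sx = sx, sy = sy, sw = sw,
                     sh = sh, px = px, py = py, pw = pw,
                     ph = ph, x1p = x1p, x2p = x2p, y1p = y1p, y2p = y2p,
                     x1g = x1g, x2g = x2g, y1g = y1g, y2g = y2g,
                     iw = iw, ih = ih, I = I, Ap = Ap, U = U,
                     gx = pos$x[r], gy = pos$y[r])
  }
  val <- total / n
  ag_node(array(val, 1L), list(box), function(g) {
    gmap <- array(0, dim(bv))
    gscale <- as.numeric(g) / n
    for (p in per) {
      # d(loss_r)/d(corner coords)
      open <- p$iw > 0 && p$ih > 0
      dI <- c(x1p = 0, x2p = 0, y1p = 0, y2p = 0)
      if (open) {
        dI["x1p"] <- -p$ih * (p$x1p > p$x1g)
        dI["x2p"] <-  p$ih * (p$x2p < p$x2g)
        dI["y1p"] <- -p$iw * (p$y1p > p$y1g)
        dI["y2p"] <-  p$iw * (p$y2p < p$y2g)
      }
      dAp <- c(x1p = -(p$y2p - p$y1p), x2p = p$y2p - p$y1p,
               y1p = -(p$x2p - p$x1p), y2p = p$x2p - p$x1p)
      dU <- dAp - dI
      # d(iou) = (dI * U - I * dU) / U^2 ; loss term is -iou
      diou <- (dI * p$U - p$I * dU) / p$U^2
      dcorn <- -diou
      # corners -> centre/size
      dpx <- dcorn[["x1p"]] + dcorn[["x2p"]]
      dpy <- dcorn[["y1p"]] + dcorn[["y2p"]]
      dpw <- (dcorn[["x2p"]] - dcorn[["x1p"]]) / 2
      dph <- (dcorn[["y2p"]] - dcorn[["y1p"]]) / 2
      base <- BOX_SIZE_MULT * stride
      dpx <- dpx + CENTER_PEN * 2 * (p$px - p$gx) / base^2
      dpy <- dpy + CENTER_PEN * 2 * (p$py - p$gy) / base^2
      # centre/size -> raw channels: dpx/dtx = 2 s sig', dpw/dtw = 2 pw (1 - sig)
      gtx <- dpx * 2 * stride * p$sx * (1 - p$sx)
      gty <- dpy * 2 * stride * p$sy * (1 - p$sy)
      gtw <- dpw * 2 * p$pw * (1 - p$sw)
      gth <- dph * 2 * p$ph * (1 - p$sh)
      gmap[p$b, 1, p$gi, p$gj] <- gmap[p$b, 1, p$gi, p$gj] + gtx * gscale
      gmap[p$b, 2, p$gi, p$gj] <- gmap[p$b, 2, p$gi, p$gj] + gty * gscale
      gmap[p$b, 3, p$gi, p$gj] <- gmap[p$b, 3, p$gi, p$gj] + gtw * gscale
      gmap[p$b, 4, p$gi, p$gj] <- gmap[p$b, 4, p$gi, p$gj] + gth * gscale
    }
    list(gmap)
  })
}

# Loss over one set of per-scale prediction nodes.
loss_from_preds <- function(preds, targets, num_classes,
                            weights = c(obj = 1, cls = 0.5, box = 2)) {
  terms <- list(obj = NULL, cls = NULL, box = NULL)
  add_term <- function(slot, node) {
    terms[[slot]] <<- if (is.null(terms[[slot]])) node
                      else ag_add(terms[[slot]], node)
  }
  for (k in seq_along(preds)) {
    pk <- preds[[k]]; tk <- targets[[k]]
    obj <- ag_slice_c(pk, 5L, 1L)
    pos_mask <- tk$t_obj
    neg_mask <- 1 - pos_mask
    n_pos <- sum(pos_mask); n_neg <- sum(neg_mask)
    if (n_pos > 0)
      add_term("obj", ag_scale(ag_bce_logits(obj, tk$t_obj, pos_mask), 0.5))
    add_term("obj", ag_scale(ag_bce_logits(obj, tk$t_obj, neg_mask), 0.5))
    if (!is.null(tk$pos)) {
      cls <- ag_slice_c(pk, 6L, num_classes)
      cls_mask <- array(pos_mask[, rep(1L, num_classes), , , drop = FALSE],
                        dim(ag_value(cls)))
      add_term("cls", ag_bce_logits(cls, tk$t_cls, cls_mask))
      add_term("box", ag_box_iou_loss(ag_slice_c(pk, 1L, 4L), tk$pos, tk$stride))
    }
  }
  zero <- function() ag_node(array(0, 1L))
  obj <- terms$obj %||% zero()
  cls <- terms$cls %||% zero()
  box <- terms$box %||% zero()
  total <- ag_add(ag_add(ag_scale(obj, weights[["obj"]]),
                         ag_scale(cls, weights[["cls"]])),
                  ag_scale(box, weights[["box"]]))
  list(total = total,
       parts = c(obj = as.numeric(ag_value(obj)),
                 cls = as.numeric(ag_value(cls)),
                 box = as.numeric(ag_value(box))))
}

# Full training loss for a batch: main predictions plus (when present)
# auxiliary-stream deep supervision at a reduced weight.
detection_loss <- function(forward_out, labels_list, input_size, num_classes,
                           aux_weight = 0.25) {
  targets <- assign_targets(labels_list, input_size, num_classes)
  main <- loss_from_preds(forward_out$preds, targets, num_classes)
  total <- main$total
  if (!is.null(forward_out$aux)) {
    aux <- loss_from_preds(forward_out$aux, targets, num_classes)
    total <- ag_add(total, ag_scale(aux$total, aux_weight))
  }
  list(total = total, parts = main$parts)
}
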