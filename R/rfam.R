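# Rough-Fine Attention Fusion Module (RFAM).
#
# Coarse stage: the two modality streams attend to each other
# (cross-attention over spatial tokens) and each attended stream is
# post-processed by its own convolutional MLP. Fine stage: directional max
# pooling collapses each coarse stream into per-column and per-row weight
# profiles (coordinate-attention style); the four profiles are spliced into
# one mixed vector, transformed by a shared MLP, split back, and used to
# re-weight the coarse streams, whose sum is the fused output.

mlp13_init <- function(c, identity = FALSE) {
  if (c < 2L || c %% 2L != 0L)
    stopf("channel count must be even and >= 2, got %d", c)
  bott <- c %/% 2L
  list(
    conv_in  = init_conv(bott, c, 3L),
    conv_mid = init_conv(bott, bott, 3L),
    conv_out = if (identity) init_conv(c, bott, 3L, mode = "zero")
               else init_conv(c, bott, 3L),
    ln       = init_ln(c),
    conv_res = if (identity) init_conv(c, c, 3L, mode = "dirac")
               else init_conv(c, c, 3L)
  )
}

mlp13_core <- function(x, m) {
  main <- ag_conv2d(x, m$conv_in$W, m$conv_in$b)
  main <- ag_conv2d(main, m$conv_mid$W, m$conv_mid$b)
  main <- ag_relu(main)
  main <- ag_conv2d(main, m$conv_out$W, m$conv_out$b)
  main <- ag_layernorm(main, m$ln$gamma, m$ln$beta)
  ag_add(main, ag_conv2d(x, m$conv_res$W, m$conv_res$b))
}

# Exact identity weights for an Eq-13-style MLP (zeroed main branch, dirac
# residual); used by the reversibility contracts and tests.
mlp13_identity <- function(c) {
  m <- mlp13_init(c, identity = TRUE)
  m$conv_in$W$value[] <- 0
  m$conv_mid$W$value[] <- 0
  m
}

#' Create RFAM block weights
#'
#' Parameters of a rough-fine fusion block for streams with `c` channels:
#' two independent coarse-fusion MLPs (one per modality), and one shared MLP
#' applied to the mixed directional-profile vector. All MLPs follow the same
#' bottleneck structure `LN(Conv(ReLU(Conv(Conv(x))))) + Conv(x)` with a
#' `c -> c/2 -> c/2 -> c` channel plan (3x3 convolutions, padding 1).
#'
#' @param c stream channel count (even, >= 2).
#' @param identity_init if `TRUE` (default) the MLPs start as exact identity
#'   maps (zeroed main branch, dirac residual) so fusion starts near
#'   pass-through; set `FALSE` for random init.
#' @return nested list of parameter leaves.
#' @export
rfam_init <- function(c, identity_init = TRUE) {
  list(
    c = c,
    mlp_rgb = mlp13_init(c, identity = identity_init),
    mlp_depth = mlp13_init(c, identity = identity_init),
    mlp_mix = mlp13_init(c, identity = identity_init)
  )
}

#' Cross-attention between two modality streams
#'
#' Both streams are flattened to spatial tokens; the first stream's queries
#' attend over the second stream's keys/values and vice versa:
#' `Attention1 = softmax(q1 k2' / sqrt(d_k)) v2`,
#' `Attention2 = softmax(q2 k1' / sqrt(d_k)) v1`.
#'
#' @param rgb,depth feature grids `(b, c, h, w)` of identical shape.
#' @return list of two token arrays `(b, h*w, c)`: `attn1` (rgb queries) and
#'   `attn2` (depth queries).
#' @export
cross_attention <- function(rgb, depth) {
  check_same_shape(ag_value(rgb), ag_value(depth), "modality streams")
  t1 <- ag_flatten(as_node(ag_value(rgb)))
  t2 <- ag_flatten(as_node(ag_value(depth)))
  list(attn1 = ag_value(ag_attention(t1, t2, t2)),
       attn2 = ag_value(ag_attention(t2, t1, t1)))
}

# tokens (B, N, C) <-> column grid (B, C, N, 1), the layout the coarse MLP
# convolves over.
ag_tokens_to_col <- function(tok) {
  tok <- as_node(tok)
  d <- dim(tok$value)
  y <- aperm(tok$value, c(1, 3, 2))
  dim(y) <- c(d[1], d[3], d[2], 1L)
  ag_node(y, list(tok), function(g) {
    dim(g) <- c(d[1], d[3], d[2])
    list(aperm(g, c(1, 3, 2)))
  })
}

coarse_fuse_core <- function(attn, h, w, m) {
  col <- ag_tokens_to_col(attn)
  col <- mlp13_core(col, m)
  d <- dim(ag_value(col))
  tok <- ag_node_col_to_tokens(col)
  ag_unflatten(tok, h, w)
}

ag_node_col_to_tokens <- function(col) {
  col <- as_node(col)
  d <- dim(col$value)
  y <- col$value
  dim(y) <- c(d[1], d[2], d[3])
  y <- aperm(y, c(1, 3, 2))
  ag_node(y, list(col), function(g) {
    g <- aperm(g, c(1, 3, 2))
    dim(g) <- d
    list(g)
  })
}

#' Coarse fusion: MLP transform of attended tokens, re-gridded
#'
#' Applies one of the block's coarse MLPs along the token axis and reshapes
#' the result back to the source spatial grid.
#'
#' @param attn token array `(b, h*w, c)` from [cross_attention()].
#' @param h,w source spatial size.
#' @param weights an Eq-13-style MLP weight set (e.g. `rfam_init(c)$mlp_rgb`).
#' @return feature grid `(b, c, h, w)`.
#' @export
coarse_fuse <- function(attn, h, w, weights) {
  av <- ag_value(attn)
  if (dim(av)[2] != h * w)
    stopf("token count %d does not match h*w = %d", dim(av)[2], h * w)
  ag_value(coarse_fuse_core(as_node(av), h, w, weights))
}

#' Directional max pooling into width and height profiles
#'
#' Collapses the height axis into a width profile `(b, c, w, 1)` and the
#' width axis into a height profile `(b, c, 1, h)` by taking maxima.
#'
#' @param grid feature grid `(b, c, h, w)`.
#' @return list with elements `w` (width profile) and `h` (height profile).
#' @export
directional_pool <- function(grid) {
  check_feature_grid(ag_value(grid), "grid")
  list(w = ag_value(ag_maxpool_axis(grid, "w")),
       h = ag_value(ag_maxpool_axis(grid, "h")))
}

#' Splice four directional profiles into one mixed vector
#'
#' Height profiles are transposed (last two dims swapped) and the four
#' profiles concatenated along the profile-length axis in the fixed order
#' `[rgb_w | depth_w | t(rgb_h) | t(depth_h)]`, giving `(b, c, 2w + 2h, 1)`.
#'
#' @param rgbw,depthw width profiles `(b, c, w, 1)`.
#' @param rgbh,depthh height profiles `(b, c, 1, h)`.
#' @return mixed vector `(b, c, 2w + 2h, 1)`.
#' @export
mix_vectors <- function(rgbw, depthw, rgbh, depthh) {
  dw <- dim(ag_value(rgbw)); dh <- dim(ag_value(rgbh))
  if (!identical(dw[1:2], dim(ag_value(depthw))[1:2]) ||
      !identical(dw[1:2], dh[1:2]) ||
      !identical(dh, dim(ag_value(depthh))))
    stopf("profiles must share batch and channel dims")
  ag_value(ag_concat_3(list(rgbw, depthw,
                            ag_trans_last2(rgbh), ag_trans_last2(depthh))))
}

split_vectors_core <- function(mixed, w, h, m, bounded = FALSE) {
  x <- mlp13_core(mixed, m)
  if (bounded) x <- ag_sigmoid(x)
  list(rgbw = ag_slice_3(x, 1L, w),
       depthw = ag_slice_3(x, w + 1L, w),
       rgbh = ag_trans_last2(ag_slice_3(x, 2L * w + 1L, h)),
       depthh = ag_trans_last2(ag_slice_3(x, 2L * w + h + 1L, h)))
}

#' Transform the mixed vector and split it back into four profiles
#'
#' The shared MLP transforms the mixed vector; the result is sliced back
#' into the four directional profiles (height profiles un-transposed). With
#' identity MLP weights this is the exact inverse of [mix_vectors()].
#'
#' @param mixed mixed vector `(b, c, 2w + 2h, 1)`.
#' @param w,h spatial extents of the source grids.
#' @param weights shared MLP weight set (e.g. `rfam_init(c)$mlp_mix`).
#' @return list `rgbw`, `depthw` (width profiles) and `rgbh`, `depthh`
#'   (height profiles).
#' @export
split_vectors <- function(mixed, w, h, weights) {
  mv <- ag_value(mixed)
  if (dim(mv)[3] != 2L * w + 2L * h)
    stopf("mixed vector length %d does not equal 2w + 2h = %d",
          dim(mv)[3], 2L * w + 2L * h)
  lapply(split_vectors_core(as_node(mv), w, h, weights), ag_value)
}

fine_fuse_core <- function(rgbR, depthR, rgbw, rgbh, depthw, depthh) {
  a <- ag_mul_hprofile(ag_mul_wprofile(rgbR, rgbw), rgbh)
  b <- ag_mul_hprofile(ag_mul_wprofile(depthR, depthw), depthh)
  ag_add(a, b)
}

#' Fine fusion of the coarse streams with directional weight profiles
#'
#' `Fused = rgbR * rgb_w * rgb_h + depthR * depth_w * depth_h`, where each
#' profile is broadcast across its collapsed axis (standard coordinate
#' attention semantics). `method = "matmul"` instead takes the printed
#' matrix-product reading literally per `(b, c)` slice,
#' `X %*% w_profile %*% h_profile`, which changes the spatial shape to
#' `(b, c, h, h)`; it is exposed for experimentation only.
#'
#' @param rgbR,depthR coarse-fused grids `(b, c, h, w)`.
#' @param rgbw,depthw width profiles `(b, c, w, 1)`.
#' @param rgbh,depthh height profiles `(b, c, 1, h)`.
#' @param method `"broadcast"` (default) or `"matmul"`.
#' @return fused grid `(b, c, h, w)` (or `(b, c, h, h)` under `"matmul"`).
#' @export
fine_fuse <- function(rgbR, depthR, rgbw, rgbh, depthw, depthh,
                      method = c("broadcast", "matmul")) {
  method <- match.arg(method)
  check_same_shape(ag_value(rgbR), ag_value(depthR), "coarse streams")
  if (method == "broadcast")
    return(ag_value(fine_fuse_core(as_node(ag_value(rgbR)), as_node(ag_value(depthR)),
                                   rgbw, rgbh, depthw, depthh)))
  d <- dim(ag_value(rgbR))
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  out <- array(0, c(B, C, H, H))
  for (b in seq_len(B)) for (cc in seq_len(C)) {
    out[b, cc, , ] <-
      matrix(ag_value(rgbR)[b, cc, , ], H, W) %*%
        matrix(ag_value(rgbw)[b, cc, , 1], W, 1) %*%
        matrix(ag_value(rgbh)[b, cc, 1, ], 1, H) +
      matrix(ag_value(depthR)[b, cc, , ], H, W) %*%
        matrix(ag_value(depthw)[b, cc, , 1], W, 1) %*%
        matrix(ag_value(depthh)[b, cc, 1, ], 1, H)
  }
  out
}

rfam_forward_core <- function(rgb, depth, w, bounded = FALSE) {
  d <- dim(ag_value(rgb))
  H <- d[3]; W <- d[4]
  t1 <- ag_flatten(rgb); t2 <- ag_flatten(depth)
  a1 <- ag_attention(t1, t2, t2)
  a2 <- ag_attention(t2, t1, t1)
  rgbR <- coarse_fuse_core(a1, H, W, w$mlp_rgb)
  depthR <- coarse_fuse_core(a2, H, W, w$mlp_depth)
  pr <- list(w = ag_maxpool_axis(rgbR, "w"), h = ag_maxpool_axis(rgbR, "h"))
  pd <- list(w = ag_maxpool_axis(depthR, "w"), h = ag_maxpool_axis(depthR, "h"))
  mixed <- ag_concat_3(list(pr$w, pd$w, ag_trans_last2(pr$h), ag_trans_last2(pd$h)))
  sv <- split_vectors_core(mixed, W, H, w$mlp_mix, bounded = bounded)
  fine_fuse_core(rgbR, depthR, sv$rgbw, sv$rgbh, sv$depthw, sv$depthh)
}

#' Full RFAM forward pass (two streams)
#'
#' Composition cross-attention -> coarse MLPs -> directional pooling ->
#' mix/MLP/split -> fine fusion. Output shape equals input shape.
#'
#' @param rgb,depth feature grids `(b, c, h, w)` of identical shape.
#' @param weights block weights from [rfam_init()].
#' @param bounded apply a sigmoid to the fine-fusion profiles (classic
#'   coordinate attention); default `FALSE`, matching the block equations.
#' @return fused feature grid `(b, c, h, w)`.
#' @export
rfam_forward <- function(rgb, depth, weights, bounded = FALSE) {
  check_same_shape(ag_value(rgb), ag_value(depth), "modality streams")
  ag_value(rfam_forward_core(as_node(ag_value(rgb)), as_node(ag_value(depth)),
                             weights, bounded = bounded))
}

#' Create tri-modal RFAM weights (two inner blocks and one outer block)
#' @param c stream channel count.
#' @param identity_init passed to [rfam_init()].
#' @return list with `inner_xy`, `inner_xz`, `outer` weight sets.
#' @export
rfam_tri_init <- function(c, identity_init = TRUE) {
  list(inner_xy = rfam_init(c, identity_init),
       inner_xz = rfam_init(c, identity_init),
       outer = rfam_init(c, identity_init))
}

#' Full RFAM forward pass (three streams)
#'
#' Nested fusion `f = RFAM(RFAM(x, y), RFAM(x, z))`; the outer block has its
#' own parameters.
#'
#' @param x,y,z feature grids `(b, c, h, w)` of identical shape.
#' @param weights from [rfam_tri_init()].
#' @param bounded see [rfam_forward()].
#' @return fused feature grid `(b, c, h, w)`.
#' @export
rfam_forward_tri <- function(x, y, z, weights, bounded = FALSE) {
  check_same_shape(ag_value(x), ag_value(y), "modality streams")
  check_same_shape(ag_value(x), ag_value(z), "modality streams")
  g1 <- rfam_forward(x, y, weights$inner_xy, bounded = bounded)
  g2 <- rfam_forward(x, z, weights$inner_xz, bounded = bounded)
  rfam_forward(g1, g2, weights$outer, bounded = bounded)
}
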