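# Local-Global Enhancement Module (LGEM).
#
# The block mixes the two modality streams, compresses the mixture to a
# one-channel *local* weight map with a small convolutional MLP, globalises
# that map with single-head self-attention over spatial tokens, and finally
# re-weights both streams multiplicatively with the resulting *global* map.

#' Create LGEM block weights
#'
#' Builds the parameter set of a local-global enhancement block for streams
#' with `c` channels each. The local MLP takes the `modalities * c`-channel
#' concatenated mixture, bottlenecks it at `c / 2` channels and compresses to
#' one channel (3x3 convolutions, stride 1, padding 1, with bias), with a
#' parallel one-conv residual and a layer norm on the main branch; the global
#' branch ends in a one-in/one-out convolution applied to the re-gridded
#' attention output.
#'
#' @param c channels per modality stream (must be even so the `c/2`
#'   bottleneck is defined).
#' @param modalities number of input streams (2 or 3).
#' @param identity_gate if `TRUE` (default) the final 1-to-1 convolution
#'   starts with weight 0 and bias 1, so the multiplicative enhancement
#'   starts near the identity; set `FALSE` for plain random init.
#' @return nested list of parameter leaves (see [ag_param()]).
#' @export
lgem_init <- function(c, modalities = 2L, identity_gate = TRUE) {
  if (c < 2L || c %% 2L != 0L)
    stopf("stream channel count must be even and >= 2, got %d", c)
  n_in <- modalities * c
  bott <- c %/% 2L
  list(
    n_in = n_in,
    mlp = list(
      conv_in  = init_conv(bott, n_in, 3L),
      conv_mid = init_conv(bott, bott, 3L),
      conv_out = init_conv(1L, bott, 3L),
      ln       = init_ln(1L),
      conv_res = init_conv(1L, n_in, 3L)
    ),
    conv_g = if (identity_gate) init_conv(1L, 1L, 3L, mode = "zero", bias = 1)
             else init_conv(1L, 1L, 3L)
  )
}

#' Concatenate modality streams on the channel axis
#'
#' @param rgb,depth feature grids `(b, c, h, w)` with identical shapes.
#' @return feature grid `(b, 2c, h, w)`; channels `1..c` are the first
#'   stream, `c+1..2c` the second.
#' @export
concat_modalities <- function(rgb, depth) {
  check_feature_grid(ag_value(rgb), "rgb")
  check_feature_grid(ag_value(depth), "depth")
  check_same_shape(ag_value(rgb), ag_value(depth), "modality streams")
  ag_value(ag_concat_c(list(rgb, depth)))
}

local_mlp_core <- function(local, w) {
  m <- w$mlp
  main <- ag_conv2d(local, m$conv_in$W, m$conv_in$b)
  main <- ag_conv2d(main, m$conv_mid$W, m$conv_mid$b)
  main <- ag_relu(main)
  main <- ag_conv2d(main, m$conv_out$W, m$conv_out$b)
  main <- ag_layernorm(main, m$ln$gamma, m$ln$beta)
  res <- ag_conv2d(local, m$conv_res$W, m$conv_res$b)
  ag_add(main, res)
}

#' Compress a mixed-modal grid to a one-channel local weight map
#'
#' Applies the block's convolutional MLP
#' `LN(Conv(ReLU(Conv(Conv(x))))) + Conv(x)` (all 3x3, stride 1, padding 1)
#' to the channel-concatenated mixture, producing a `(b, 1, h, w)` map.
#'
#' @param local mixed feature grid `(b, 2c, h, w)` (or `3c` tri-modal).
#' @param weights block weights from [lgem_init()].
#' @return local weight map `(b, 1, h, w)`.
#' @export
local_mlp <- function(local, weights) {
  lv <- ag_value(local)
  check_feature_grid(lv, "local")
  if (dim(lv)[2] %% 2L != 0L)
    stopf("mixed grid must have an even channel count, got %d", dim(lv)[2])
  if (dim(lv)[2] != weights$n_in)
    stopf("mixed grid has %d channels but weights expect %d",
          dim(lv)[2], weights$n_in)
  ag_value(local_mlp_core(local, weights))
}

#' Flatten a feature grid into a token sequence
#'
#' Pure reshape of a `(b, c, h, w)` grid into a `(b, h*w, c)` token array:
#' spatial positions are tokens, channels are token features. Exact inverse
#' of [upsample_tokens()].
#'
#' @param grid feature grid.
#' @return token array `(b, h*w, c)`.
#' @export
flatten_tokens <- function(grid) {
  check_feature_grid(ag_value(grid), "grid")
  ag_value(ag_flatten(grid))
}

#' Re-grid a token sequence (inverse of [flatten_tokens()])
#'
#' @param tokens token array `(b, n, c)` with `n = h * w`.
#' @param h,w target spatial size.
#' @return feature grid `(b, c, h, w)`.
#' @export
upsample_tokens <- function(tokens, h, w) {
  tv <- ag_value(tokens)
  if (length(dim(tv)) != 3L) stopf("tokens must be a 3-d (b, n, c) array")
  ag_value(ag_unflatten(tokens, h, w))
}

#' Single-head scaled dot-product self-attention over tokens
#'
#' `softmax(q k' / sqrt(d_k)) v` with the softmax over the key-token axis and
#' `d_k` the token feature (channel) dimension.
#'
#' @param q,k,v token arrays `(b, n, d)` of identical shape.
#' @return attended token array `(b, n, d)`.
#' @export
self_attention <- function(q, k, v) {
  ag_value(ag_attention(q, k, v))
}

#' Build the global weight map from attended tokens
#'
#' Re-grids the attention output back to `(b, 1, h, w)` and applies the
#' block's one-in/one-out convolution.
#'
#' @param attn attended token array `(b, h*w, 1)`.
#' @param h,w spatial size of the source grid.
#' @param weights block weights from [lgem_init()] (uses `conv_g`).
#' @return global weight map `(b, 1, h, w)`.
#' @export
global_weight <- function(attn, h, w, weights) {
  av <- ag_value(attn)
  if (dim(av)[2] != h * w)
    stopf("attention length %d does not match h*w = %d", dim(av)[2], h * w)
  grid <- ag_unflatten(attn, h, w)
  ag_value(ag_conv2d(grid, weights$conv_g$W, weights$conv_g$b))
}

#' Multiplicatively enhance modality streams with a global weight map
#'
#' Each stream is multiplied elementwise by the one-channel map, broadcast
#' across its feature channels.
#'
#' @param rgb,depth feature grids `(b, c, h, w)`.
#' @param eglobal weight map `(b, 1, h, w)`.
#' @return list with enhanced `rgb` and `depth` grids.
#' @export
enhance <- function(rgb, depth, eglobal) {
  list(rgb = ag_value(ag_mul_map(rgb, eglobal)),
       depth = ag_value(ag_mul_map(depth, eglobal)))
}

lgem_forward_core <- function(streams, w) {
  local <- ag_concat_c(streams)
  elocal <- local_mlp_core(local, w)
  d <- dim(ag_value(elocal))
  tok <- ag_flatten(elocal)
  attn <- ag_attention(tok, tok, tok)
  eglobal <- ag_conv2d(ag_unflatten(attn, d[3], d[4]), w$conv_g$W, w$conv_g$b)
  stopifnot(dim(ag_value(eglobal))[2] == 1L)
  lapply(streams, function(s) ag_mul_map(s, eglobal))
}

#' Full LGEM forward pass (two streams)
#'
#' Composition concat -> local MLP -> flatten -> self-attention -> global
#' weight -> multiplicative enhancement. Output shapes equal input shapes.
#'
#' @param rgb,depth feature grids `(b, c, h, w)` of identical shape.
#' @param weights block weights from [lgem_init()].
#' @return list with enhanced `rgb` and `depth` grids.
#' @export
lgem_forward <- function(rgb, depth, weights) {
  check_same_shape(ag_value(rgb), ag_value(depth), "modality streams")
  out <- lgem_forward_core(list(as_node(ag_value(rgb)), as_node(ag_value(depth))),
                           weights)
  list(rgb = out[[1]]$value, depth = out[[2]]$value)
}

#' Full LGEM forward pass (three streams)
#'
#' Tri-modal variant: the mixture is the channel concatenation of all three
#' streams (the local MLP's input width is `3c`) and the shared global map
#' enhances each stream.
#'
#' @param x,y,z feature grids `(b, c, h, w)` of identical shape.
#' @param weights block weights from `lgem_init(c, modalities = 3)`.
#' @return list of three enhanced grids `x`, `y`, `z`.
#' @export
lgem_forward_tri <- function(x, y, z, weights) {
  check_same_shape(ag_value(x), ag_value(y), "modality streams")
  check_same_shape(ag_value(x), ag_value(z), "modality streams")
  out <- lgem_forward_core(list(as_node(ag_value(x)), as_node(ag_value(y)),
                                as_node(ag_value(z))), weights)
  list(x = out[[1]]$value, y = out[[2]]$value, z = out[[3]]$value)
}
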