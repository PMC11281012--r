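# Rough-fine fusion block: cross-attention, coarse MLPs, directional
# pooling, mix/split reversibility, fine fusion, and the full chain.

test_that("cross_attention is symmetric on identical inputs and matches the
           brute-force oracle", {
  set.seed(11)
  rgb <- rand_grid(1, 2, 1, 3)   # three spatial tokens
  dep <- rand_grid(1, 2, 1, 3)
  ca <- cross_attention(rgb, dep)
  t1 <- flatten_tokens(rgb); t2 <- flatten_tokens(dep)
  expect_lt(max(abs(ca$attn1 - r_attention(t1, t2, t2))), 1e-6)
  expect_lt(max(abs(ca$attn2 - r_attention(t2, t1, t1))), 1e-6)
  same <- cross_attention(rgb, rgb)
  expect_identical(same$attn1, same$attn2)
  # single spatial position: attention collapses to the other stream's value
  r1 <- rand_grid(2, 3, 1, 1); d1 <- rand_grid(2, 3, 1, 1)
  one <- cross_attention(r1, d1)
  expect_equal(one$attn1, flatten_tokens(d1))
  expect_equal(one$attn2, flatten_tokens(r1))
  expect_error(cross_attention(rgb, rand_grid(1, 2, 3, 1)), "share one shape")
})

test_that("coarse_fuse applies the bottleneck MLP along tokens and re-grids", {
  set.seed(12)
  w <- rfam_init(4, identity_init = FALSE)
  attn <- array(rnorm(1 * 6 * 4), c(1, 6, 4))
  out <- coarse_fuse(attn, 2, 3, w$mlp_rgb)
  expect_identical(dim(out), c(1L, 4L, 2L, 3L))
  zw <- rfam_init(4); zero_weights(zw)
  expect_equal(coarse_fuse(attn, 2, 3, zw$mlp_rgb), array(0, c(1, 4, 2, 3)))
  # oracle: column-layout conv chain + slice back
  col <- aperm(attn, c(1, 3, 2)); dim(col) <- c(1, 4, 6, 1)
  ocol <- r_mlp13(col, w$mlp_rgb)
  dim(ocol) <- c(1, 4, 6)
  oracle <- upsample_tokens(aperm(ocol, c(1, 3, 2)), 2, 3)
  expect_lt(max(abs(out - oracle)), 1e-6)
  expect_error(coarse_fuse(attn, 3, 3, w$mlp_rgb), "does not match")
})

test_that("directional_pool takes maxima and keeps the printed shapes", {
  set.seed(13)
  const <- array(5, c(2, 3, 4, 6))
  p <- directional_pool(const)
  expect_true(all(p$w == 5) && all(p$h == 5))
  x <- rand_grid(2, 3, 4, 6)
  p <- directional_pool(x)
  expect_identical(dim(p$w), c(2L, 3L, 6L, 1L))
  expect_identical(dim(p$h), c(2L, 3L, 1L, 4L))
  for (b in 1:2) for (cc in 1:3) {
    for (j in 1:6) expect_equal(p$w[b, cc, j, 1], max(x[b, cc, , j]))
    for (i in 1:4) expect_equal(p$h[b, cc, 1, i], max(x[b, cc, i, ]))
  }
})

test_that("mix_vectors splices in the fixed order and split_vectors with an
           identity MLP is its exact inverse", {
  set.seed(14)
  B <- 2; C <- 4; W <- 4; H <- 3
  rw <- array(rnorm(B * C * W), c(B, C, W, 1))
  dw <- array(rnorm(B * C * W), c(B, C, W, 1))
  rh <- array(rnorm(B * C * H), c(B, C, 1, H))
  dh <- array(rnorm(B * C * H), c(B, C, 1, H))
  mx <- mix_vectors(rw, dw, rh, dh)
  expect_identical(dim(mx), c(2L, 4L, 14L, 1L))   # 2*4 + 2*3
  expect_identical(mx[, , 1:W, , drop = FALSE], rw)
  expect_identical(mx[, , W + 1:W, , drop = FALSE], dw)
  idw <- rgbdet:::mlp13_identity(C)
  sv <- split_vectors(mx, W, H, idw)
  expect_identical(sv$rgbw, rw)
  expect_identical(sv$depthw, dw)
  expect_identical(sv$rgbh, rh)
  expect_identical(sv$depthh, dh)
  expect_error(mix_vectors(rw, dw[, 1:2, , , drop = FALSE], rh, dh),
               "batch and channel")
  expect_error(split_vectors(mx, W, H + 1, idw), "does not equal")
})

test_that("split_vectors with random weights equals MLP-then-slice", {
  set.seed(15)
  B <- 1; C <- 4; W <- 3; H <- 2
  mx <- array(rnorm(B * C * (2 * W + 2 * H)), c(B, C, 2 * W + 2 * H, 1))
  w <- rfam_init(C, identity_init = FALSE)
  sv <- split_vectors(mx, W, H, w$mlp_mix)
  o <- r_mlp13(mx, w$mlp_mix)
  expect_lt(max(abs(sv$rgbw - o[, , 1:W, , drop = FALSE])), 1e-6)
  expect_lt(max(abs(sv$depthw - o[, , W + 1:W, , drop = FALSE])), 1e-6)
  expect_lt(max(abs(sv$rgbh - aperm(o[, , 2 * W + 1:H, , drop = FALSE],
                                    c(1, 2, 4, 3)))), 1e-6)
  expect_lt(max(abs(sv$depthh - aperm(o[, , 2 * W + H + 1:H, , drop = FALSE],
                                      c(1, 2, 4, 3)))), 1e-6)
})

test_that("fine_fuse is the profile-weighted sum of the two streams", {
  set.seed(16)
  B <- 2; C <- 3; H <- 3; W <- 4
  rgbR <- rand_grid(B, C, H, W); depR <- rand_grid(B, C, H, W)
  ones_w <- array(1, c(B, C, W, 1)); ones_h <- array(1, c(B, C, 1, H))
  expect_equal(fine_fuse(rgbR, depR, ones_w, ones_h, ones_w, ones_h),
               rgbR + depR)
  zw <- array(0, c(B, C, W, 1)); zh <- array(0, c(B, C, 1, H))
  rw <- array(rnorm(B * C * W), c(B, C, W, 1))
  rh <- array(rnorm(B * C * H), c(B, C, 1, H))
  only_rgb <- fine_fuse(rgbR, depR, rw, rh, zw, zh)
  # explicit triple-loop oracle
  oracle <- array(0, c(B, C, H, W))
  for (b in seq_len(B)) for (cc in seq_len(C)) for (i in seq_len(H))
    for (j in seq_len(W))
      oracle[b, cc, i, j] <- rgbR[b, cc, i, j] * rw[b, cc, j, 1] * rh[b, cc, 1, i]
  expect_lt(max(abs(only_rgb - oracle)), 1e-6)
  # bilinearity: scaling one profile scales that stream's contribution
  dw <- array(rnorm(B * C * W), c(B, C, W, 1))
  dh <- array(rnorm(B * C * H), c(B, C, 1, H))
  f1 <- fine_fuse(rgbR, depR, rw, rh, dw, dh)
  f2 <- fine_fuse(rgbR, depR, rw * 3, rh, dw, dh)
  rgb_part <- fine_fuse(rgbR, depR, rw, rh, zw, zh)
  expect_equal(f2 - f1, 2 * rgb_part)
})

test_that("fine_fuse matmul variant takes the printed product literally", {
  set.seed(17)
  B <- 1; C <- 2; H <- 3; W <- 4
  rgbR <- rand_grid(B, C, H, W); depR <- rand_grid(B, C, H, W)
  rw <- array(rnorm(B * C * W), c(B, C, W, 1)); dw <- array(rnorm(B * C * W), c(B, C, W, 1))
  rh <- array(rnorm(B * C * H), c(B, C, 1, H)); dh <- array(rnorm(B * C * H), c(B, C, 1, H))
  out <- fine_fuse(rgbR, depR, rw, rh, dw, dh, method = "matmul")
  expect_identical(dim(out), c(1L, 2L, 3L, 3L))   # (h, h): shape changes
  o11 <- matrix(rgbR[1, 1, , ], H, W) %*% matrix(rw[1, 1, , 1], W, 1) %*%
    matrix(rh[1, 1, 1, ], 1, H) +
    matrix(depR[1, 1, , ], H, W) %*% matrix(dw[1, 1, , 1], W, 1) %*%
    matrix(dh[1, 1, 1, ], 1, H)
  expect_lt(max(abs(out[1, 1, , ] - o11)), 1e-10)
})

test_that("rfam_forward preserves shape, is deterministic, and equals the
           chained composition of its primitives", {
  set.seed(18)
  w <- rfam_init(8, identity_init = FALSE)
  rgb <- rand_grid(2, 8, 4, 4); dep <- rand_grid(2, 8, 4, 4)
  f1 <- rfam_forward(rgb, dep, w)
  f2 <- rfam_forward(rgb, dep, w)
  expect_identical(dim(f1), dim(rgb))
  expect_identical(f1, f2)
  ca <- cross_attention(rgb, dep)
  r1 <- coarse_fuse(ca$attn1, 4, 4, w$mlp_rgb)
  r2 <- coarse_fuse(ca$attn2, 4, 4, w$mlp_depth)
  p1 <- directional_pool(r1); p2 <- directional_pool(r2)
  mx <- mix_vectors(p1$w, p2$w, p1$h, p2$h)
  sv <- split_vectors(mx, 4, 4, w$mlp_mix)
  oracle <- fine_fuse(r1, r2, sv$rgbw, sv$rgbh, sv$depthw, sv$depthh)
  expect_lt(max(abs(f1 - oracle)), 1e-6)
})

test_that("the bounded-weights flag squashes the fine-fusion profiles", {
  set.seed(19)
  w <- rfam_init(4, identity_init = FALSE)
  rgb <- rand_grid(1, 4, 3, 3); dep <- rand_grid(1, 4, 3, 3)
  plain <- rfam_forward(rgb, dep, w)
  bounded <- rfam_forward(rgb, dep, w, bounded = TRUE)
  expect_false(isTRUE(all.equal(plain, bounded)))
  ca <- cross_attention(rgb, dep)
  r1 <- coarse_fuse(ca$attn1, 3, 3, w$mlp_rgb)
  r2 <- coarse_fuse(ca$attn2, 3, 3, w$mlp_depth)
  p1 <- directional_pool(r1); p2 <- directional_pool(r2)
  mx <- mix_vectors(p1$w, p2$w, p1$h, p2$h)
  tr <- r_mlp13(mx, w$mlp_mix)
  sq <- 1 / (1 + exp(-tr))
  W <- 3; H <- 3
  oracle <- fine_fuse(r1, r2, sq[, , 1:W, , drop = FALSE],
                      aperm(sq[, , 2 * W + 1:H, , drop = FALSE], c(1, 2, 4, 3)),
                      sq[, , W + 1:W, , drop = FALSE],
                      aperm(sq[, , 2 * W + H + 1:H, , drop = FALSE], c(1, 2, 4, 3)))
  expect_lt(max(abs(bounded - oracle)), 1e-6)
})

test_that("tri-modal rfam nests two inner fusions under an outer one", {
  set.seed(20)
  w <- rfam_tri_init(4, identity_init = FALSE)
  x <- rand_grid(1, 4, 3, 3); y <- rand_grid(1, 4, 3, 3); z <- rand_grid(1, 4, 3, 3)
  f <- rfam_forward_tri(x, y, z, w)
  expect_identical(dim(f), dim(x))
  g1 <- rfam_forward(x, y, w$inner_xy)
  g2 <- rfam_forward(x, z, w$inner_xz)
  expect_lt(max(abs(f - rfam_forward(g1, g2, w$outer))), 1e-6)
  # weight-tied blocks with z == y collapse to RFAM(g, g)
  tied <- list(inner_xy = w$inner_xy, inner_xz = w$inner_xy, outer = w$inner_xy)
  ft <- rfam_forward_tri(x, y, y, tied)
  g <- rfam_forward(x, y, w$inner_xy)
  expect_lt(max(abs(ft - rfam_forward(g, g, w$inner_xy))), 1e-10)
  expect_error(rfam_forward_tri(x, y, rand_grid(1, 4, 3, 4), w), "share one shape")
})
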