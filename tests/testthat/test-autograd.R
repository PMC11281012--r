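# Finite-difference verification of the compute engine's gradients: every
# trainable operation's analytic backward pass against central differences.

ns <- getNamespace("rgbdet")

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
`%||%` <- function(a, b) if (is.null(a)) b else a

scalar_of <- function(node, tgt) ns$ag_mean(ns$ag_mul(node, ns$as_node(tgt)))

test_that("convolution gradients match finite differences", {
  set.seed(21)
  x <- rand_grid(1, 2, 4, 5)
  W <- array(rnorm(3 * 2 * 3 * 3), c(3, 2, 3, 3))
  b <- rnorm(3)
  for (stride in c(1L, 2L)) {
    xn <- ns$ag_param(x); Wn <- ns$ag_param(W); bn <- ns$ag_param(b)
    out <- ns$ag_conv2d(xn, Wn, bn, stride = stride)
    tgt <- array(rnorm(length(out$value)), dim(out$value))
    ns$ag_backward(scalar_of(out, tgt))
    f <- function(which) function(v) {
      a <- list(x = x, W = W, b = b); a[[which]] <- v
      mean(ns$cpp_conv2d_forward(a$x, a$W, a$b, stride, 1L) * tgt)
    }
    expect_lt(max(abs(xn$grad - num_grad(f("x"), x))), 1e-6)
    expect_lt(max(abs(Wn$grad - num_grad(f("W"), W))), 1e-6)
    expect_lt(max(abs(bn$grad - num_grad(f("b"), b))), 1e-6)
  }
})

test_that("layer norm gradients match finite differences", {
  set.seed(22)
  x <- rand_grid(2, 3, 2, 2)
  gam <- rnorm(3); bet <- rnorm(3)
  xn <- ns$ag_param(x); gn <- ns$ag_param(gam); bn <- ns$ag_param(bet)
  out <- ns$ag_layernorm(xn, gn, bn)
  tgt <- array(rnorm(length(out$value)), dim(out$value))
  ns$ag_backward(scalar_of(out, tgt))
  fwd <- function(xx, gg = gam, bb = bet)
    mean(ns$ag_layernorm(ns$as_node(xx), ns$as_node(gg), ns$as_node(bb))$value * tgt)
  expect_lt(max(abs(xn$grad - num_grad(function(v) fwd(v), x))), 1e-6)
  expect_lt(max(abs(gn$grad - num_grad(function(v) fwd(x, v), gam))), 1e-6)
  expect_lt(max(abs(bn$grad - num_grad(function(v) fwd(x, gam, v), bet))), 1e-6)
})

test_that("attention gradients match finite differences", {
  set.seed(23)
  q <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
  k <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
  v <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
  qn <- ns$ag_param(q); kn <- ns$ag_param(k); vn <- ns$ag_param(v)
  out <- ns$ag_attention(qn, kn, vn)
  tgt <- array(rnorm(length(out$value)), dim(out$value))
  ns$ag_backward(scalar_of(out, tgt))
  fwd <- function(qq, kk = k, vv = v) mean(r_attention(qq, kk, vv) * tgt)
  expect_lt(max(abs(qn$grad - num_grad(function(x) fwd(x), q))), 1e-6)
  expect_lt(max(abs(kn$grad - num_grad(function(x) fwd(q, x), k))), 1e-6)
  expect_lt(max(abs(vn$grad - num_grad(function(x) fwd(q, k, x), v))), 1e-6)
})

test_that("pooling, upsampling and broadcast-product gradients match finite
           differences", {
  set.seed(24)
  x <- rand_grid(2, 2, 3, 4)
  for (op in list(function(n) ns$ag_maxpool_axis(n, "w"),
                  function(n) ns$ag_maxpool_axis(n, "h"),
                  function(n) ns$ag_maxpool2d(n, 3L),
                  ns$ag_upsample2)) {
    xn <- ns$ag_param(x)
    out <- op(xn)
    tgt <- array(rnorm(length(out$value)), dim(out$value))
    ns$ag_backward(scalar_of(out, tgt))
    gnum <- num_grad(function(v) mean(op(ns$as_node(v))$value * tgt), x)
    expect_lt(max(abs(xn$grad - gnum)), 1e-6)
  }
  pw <- array(rnorm(2 * 2 * 4), c(2, 2, 4, 1))
  ph <- array(rnorm(2 * 2 * 3), c(2, 2, 1, 3))
  xn <- ns$ag_param(x); pn <- ns$ag_param(pw); hn <- ns$ag_param(ph)
  out <- ns$ag_mul_hprofile(ns$ag_mul_wprofile(xn, pn), hn)
  tgt <- array(rnorm(length(out$value)), dim(out$value))
  ns$ag_backward(scalar_of(out, tgt))
  fwd <- function(xx, ww = pw, hh = ph) {
    o <- array(0, dim(x))
    for (b in 1:2) for (cc in 1:2) for (i in 1:3) for (j in 1:4)
      o[b, cc, i, j] <- xx[b, cc, i, j] * ww[b, cc, j, 1] * hh[b, cc, 1, i]
    mean(o * tgt)
  }
  expect_lt(max(abs(xn$grad - num_grad(function(v) fwd(v), x))), 1e-6)
  expect_lt(max(abs(pn$grad - num_grad(function(v) fwd(x, v), pw))), 1e-6)
  expect_lt(max(abs(hn$grad - num_grad(function(v) fwd(x, pw, v), ph))), 1e-6)
})

test_that("loss gradients (BCE-with-logits and IoU box term) match finite
           differences", {
  set.seed(25)
  z <- rand_grid(2, 1, 3, 3)
  t <- array(rbinom(18, 1, 0.4), dim(z))
  w <- array(runif(18), dim(z))
  zn <- ns$ag_param(z)
  ns$ag_backward(ns$ag_bce_logits(zn, t, w))
  fwd <- function(v) {
    lo <- pmax(v, 0) - v * t + log1p(exp(-abs(v)))
    sum(lo * w) / sum(w)
  }
  expect_lt(max(abs(zn$grad - num_grad(fwd, z))), 1e-6)

  box <- array(rnorm(1 * 4 * 4 * 4, sd = 0.5), c(1, 4, 4, 4))
  pos <- data.frame(b = 1, gi = c(2, 3), gj = c(3, 2),
                    x = c(38, 24), y = c(25, 44), w = c(30, 22), h = c(26, 28))
  bn <- ns$ag_param(box)
  ns$ag_backward(ns$ag_box_iou_loss(bn, pos, 16))
  gnum <- num_grad(function(v)
    as.numeric(ns$ag_box_iou_loss(ns$as_node(v), pos, 16)$value), box, eps = 1e-6)
  expect_lt(max(abs(bn$grad - gnum)), 1e-4)
})

test_that("gradients reach every parameter through a full LGEM + RFAM chain", {
  set.seed(26)
  wl <- lgem_init(4, identity_gate = FALSE)
  wr <- rfam_init(4, identity_init = FALSE)
  randomize_weights(wl); randomize_weights(wr)
  params <- c(ns$collect_params(wl), ns$collect_params(wr))
  ns$ag_zero_grad(params)
  rgb <- rand_grid(1, 4, 3, 3); dep <- rand_grid(1, 4, 3, 3)
  enh <- ns$lgem_forward_core(list(ns$as_node(rgb), ns$as_node(dep)), wl)
  fused <- ns$rfam_forward_core(enh[[1]], enh[[2]], wr)
  ns$ag_backward(ns$ag_mean(ns$ag_mul(fused, fused)))
  expect_true(all(vapply(params, function(p) !is.null(p$grad), logical(1))))
  # spot-check one deep parameter against finite differences
  p <- wl$mlp$conv_in$W
  f <- function(v) {
    old <- p$value; p$value <- v
    on.exit(p$value <- old)
    e <- ns$lgem_forward_core(list(ns$as_node(rgb), ns$as_node(dep)), wl)
    mean(ns$rfam_forward_core(e[[1]], e[[2]], wr)$value^2)
  }
  idx <- sample(length(p$value), 4)
  for (i in idx) {
    eps <- 1e-5
    vp <- p$value; vp[i] <- vp[i] + eps
    vm <- p$value; vm[i] <- vm[i] - eps
    expect_lt(abs(p$grad[i] - (f(vp) - f(vm)) / (2 * eps)), 1e-4)
  }
})
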