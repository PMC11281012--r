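# Shared fixtures and independent pure-R oracles. The oracles deliberately
# avoid the package's compute engine: convolutions and attention are written
# as explicit loops so block outputs can be checked against a second path.

rand_grid <- function(b, c, h, w, sd = 1) {
  array(rnorm(b * c * h * w, sd = sd), c(b, c, h, w))
}

# give every parameter in a weight list random values
randomize_weights <- function(w, sd = 0.3) {
  for (p in rgbdet:::collect_params(w)) p$value[] <- rnorm(length(p$value), sd = sd)
  invisible(w)
}

zero_weights <- function(w) {
  for (p in rgbdet:::collect_params(w)) p$value[] <- 0
  invisible(w)
}

# explicit-loop 2-d convolution (stride 1, padding (k-1)/2)
r_conv2d <- function(x, W, bias) {
  dx <- dim(x); dw <- dim(W)
  B <- dx[1]; C <- dx[2]; H <- dx[3]; Wd <- dx[4]
  O <- dw[1]; K <- dw[3]; pad <- (K - 1) %/% 2
  y <- array(0, c(B, O, H, Wd))
  for (b in seq_len(B)) for (o in seq_len(O)) for (i in seq_len(H))
    for (j in seq_len(Wd)) {
      acc <- bias[o]
      for (ci in seq_len(C)) for (p in seq_len(K)) for (q in seq_len(K)) {
        hh <- i + p - 1 - pad; ww <- j + q - 1 - pad
        if (hh >= 1 && hh <= H && ww >= 1 && ww <= Wd)
          acc <- acc + x[b, ci, hh, ww] * W[o, ci, p, q]
      }
      y[b, o, i, j] <- acc
    }
  y
}

# layer norm over (c, h, w) per sample with per-channel affine
r_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (b in seq_len(d[1])) {
    v <- x[b, , , , drop = FALSE]
    mu <- mean(v); va <- mean(v^2) - mu^2
    for (cc in seq_len(d[2]))
      y[b, cc, , ] <- (x[b, cc, , ] - mu) / sqrt(va + eps) * gamma[cc] + beta[cc]
  }
  y
}

# brute-force scaled dot-product attention over (B, N, D) tokens
r_attention <- function(q, k, v) {
  d <- dim(q)
  B <- d[1]; N <- d[2]; D <- d[3]
  out <- array(0, d)
  for (b in seq_len(B)) for (i in seq_len(N)) {
    s <- numeric(N)
    for (j in seq_len(N)) s[j] <- sum(q[b, i, ] * k[b, j, ]) / sqrt(D)
    a <- exp(s - max(s)); a <- a / sum(a)
    for (dd in seq_len(D)) out[b, i, dd] <- sum(a * v[b, , dd])
  }
  out
}

# attention weight matrix of one batch element (for row-sum checks)
r_attention_rows <- function(q, k, b = 1) {
  d <- dim(q)
  N <- d[2]; D <- d[3]
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    s <- numeric(N)
    for (j in seq_len(N)) s[j] <- sum(q[b, i, ] * k[b, j, ]) / sqrt(D)
    a <- exp(s - max(s)); A[i, ] <- a / sum(a)
  }
  A
}

# the Eq-13-style MLP computed with the pure-R primitives, on the column
# layout (B, C, L, 1) the blocks convolve over
r_mlp13 <- function(x, m) {
  val <- function(p) rgbdet:::ag_value(p)
  main <- r_conv2d(x, val(m$conv_in$W), val(m$conv_in$b))
  main <- r_conv2d(main, val(m$conv_mid$W), val(m$conv_mid$b))
  main <- pmax(main, 0)
  main <- r_conv2d(main, val(m$conv_out$W), val(m$conv_out$b))
  main <- r_layernorm(main, val(m$ln$gamma), val(m$ln$beta))
  main + r_conv2d(x, val(m$conv_res$W), val(m$conv_res$b))
}

# in-memory easy scenes as image_pair objects
make_easy_pairs <- function(idx, base_seed = 0L) {
  cfg <- scene_config(preset = "easy", seed = base_seed)
  lapply(idx, function(i) {
    ci <- cfg; ci$seed <- base_seed + i
    s <- generate_scene(ci)
    structure(list(rgb = s$rgb, depth = s$depth, ir = NULL, labels = s$labels),
              class = "image_pair")
  })
}

# jittered predictions for one ground-truth set: each prediction clearly
# corresponds to one gt (high IoU with it, low with the rest)
jitter_preds <- function(gts, conf = NULL, shift = 1) {
  n <- nrow(gts)
  tibble::tibble(
    image = if ("image" %in% names(gts)) gts$image else rep(1L, n),
    x_min = gts$x_min + runif(n, -shift, shift),
    y_min = gts$y_min + runif(n, -shift, shift),
    x_max = gts$x_max + runif(n, -shift, shift),
    y_max = gts$y_max + runif(n, -shift, shift),
    class_id = gts$class_id,
    confidence = if (is.null(conf)) runif(n, 0.5, 1) else conf)
}
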