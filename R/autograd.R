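# Reverse-mode differentiation over plain numeric arrays.
#
# A node is an environment holding `value`, its `parents` (other nodes), and a
# `backward` closure that maps the node's output gradient to a list of parent
# gradients. Calling ag_backward() on a scalar loss node walks the graph in
# reverse topological order. Every operation also works on plain arrays (they
# are wrapped as constant leaves), which is how the functional block API below
# shares one code path with training.

.ag_state <- new.env(parent = emptyenv())
.ag_state$id <- 0L

ag_node <- function(value, parents = list(), backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$parents <- parents
  n$backward <- backward
  n$grad <- NULL
  n$is_param <- FALSE
  .ag_state$id <- .ag_state$id + 1L
  n$id <- .ag_state$id
  class(n) <- "ag_node"
  n
}

#' Create a trainable parameter leaf
#'
#' @param value numeric array holding the initial parameter values.
#' @return an autograd leaf node whose gradient is populated by
#'   [ag_backward()].
#' @keywords internal
ag_param <- function(value) {
  n <- ag_node(value)
  n$is_param <- TRUE
  n
}

as_node <- function(x) if (inherits(x, "ag_node")) x else ag_node(x)

#' Extract the value carried by a node (identity on plain arrays)
#' @param x node or array.
#' @keywords internal
ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# Reverse topological order by iterative depth-first search.
ag_toposort <- function(root) {
  order <- vector("list", 64L)
  n_out <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents)
        if (is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      n_out <- n_out + 1L
      if (n_out > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_out]] <- node
    }
  }
  order[seq_len(n_out)]
}

#' Run backpropagation from a scalar loss node
#'
#' @param loss node with a length-1 value.
#' @keywords internal
ag_backward <- function(loss) {
  if (length(loss$value) != 1L) stopf("ag_backward needs a scalar loss")
  order <- ag_toposort(loss)
  loss$grad <- array(1, dim = dim(loss$value) %||% 1L)
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$backward) || is.null(node$grad)) next
    grads <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      g <- grads[[j]]
      if (is.null(g)) next
      p <- node$parents[[j]]
      if (is.null(p$backward) && !p$is_param) next  # constant leaf
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (!node$is_param && !is.null(node$backward)) node$grad <- NULL
  }
  invisible(loss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

keep_dim <- function(g, d) { dim(g) <- d; g }

## ---- arithmetic ----

ag_add <- function(x, y) {
  x <- as_node(x); y <- as_node(y)
  check_same_shape(x$value, y$value, "addends")
  ag_node(x$value + y$value, list(x, y), function(g) list(g, g))
}

ag_mul <- function(x, y) {
  x <- as_node(x); y <- as_node(y)
  check_same_shape(x$value, y$value, "factors")
  xv <- x$value; yv <- y$value
  ag_node(xv * yv, list(x, y), function(g) list(g * yv, g * xv))
}

ag_scale <- function(x, a) {
  x <- as_node(x)
  ag_node(x$value * a, list(x), function(g) list(g * a))
}

ag_relu <- function(x) {
  x <- as_node(x)
  mask <- x$value > 0
  ag_node(x$value * mask, list(x), function(g) list(g * mask))
}

ag_sigmoid <- function(x) {
  x <- as_node(x)
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

## ---- convolution ----

#' 2-d convolution (NCHW, square kernel, bias always present)
#' @keywords internal
ag_conv2d <- function(x, W, b, stride = 1L, pad = NULL) {
  x <- as_node(x); W <- as_node(W); b <- as_node(b)
  kh <- dim(W$value)[3]
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  y <- cpp_conv2d_forward(x$value, W$value, as.numeric(b$value),
                          as.integer(stride), as.integer(pad))
  xv <- x$value; Wv <- W$value
  ag_node(y, list(x, W, b), function(g) {
    bw <- cpp_conv2d_backward(xv, Wv, g, as.integer(stride), as.integer(pad))
    list(bw$gx, bw$gW, bw$gb)
  })
}

## ---- normalisation ----

# Layer normalisation over the channel-and-spatial extent of each sample,
# with a per-channel affine transform (gamma, beta of length C).
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  d <- dim(x$value)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  N <- C * H * W
  M <- matrix(x$value, nrow = B)
  mu <- rowMeans(M)
  va <- rowMeans(M^2) - mu^2
  inv <- 1 / sqrt(va + eps)
  xhat <- (M - mu) * inv
  gvec <- rep(as.numeric(gamma$value), times = H * W)
  bvec <- rep(as.numeric(beta$value), times = H * W)
  y <- sweep(xhat, 2, gvec, `*`)
  y <- sweep(y, 2, bvec, `+`)
  ag_node(keep_dim(y, d), list(x, gamma, beta), function(g) {
    G <- matrix(g, nrow = B)
    gxhat <- sweep(G, 2, gvec, `*`)
    m1 <- rowMeans(gxhat)
    m2 <- rowMeans(gxhat * xhat)
    gx <- (gxhat - m1 - xhat * m2) * inv
    gs <- G * xhat
    # collapse (b, h, w) keeping channel
    gg <- rowSums(matrix(colSums(gs), nrow = C))
    gb <- rowSums(matrix(colSums(G), nrow = C))
    list(keep_dim(gx, d), gg, gb)
  })
}

## ---- reshaping ----

# (B, C, H, W) -> token array (B, N = H*W, D = C); token t = h + H * (w - 1).
ag_flatten <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  y <- aperm(x$value, c(1, 3, 4, 2))
  dim(y) <- c(B, H * W, C)
  ag_node(y, list(x), function(g) {
    dim(g) <- c(B, H, W, C)
    list(aperm(g, c(1, 4, 2, 3)))
  })
}

ag_unflatten <- function(tok, H, W) {
  tok <- as_node(tok)
  d <- dim(tok$value)
  B <- d[1]; N <- d[2]; C <- d[3]
  if (N != H * W) stopf("token count %d does not match h*w = %d", N, H * W)
  y <- tok$value
  dim(y) <- c(B, H, W, C)
  y <- aperm(y, c(1, 4, 2, 3))
  ag_node(y, list(tok), function(g) {
    g <- aperm(g, c(1, 3, 4, 2))
    dim(g) <- c(B, N, C)
    list(g)
  })
}

## ---- attention ----

row_softmax <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# Scaled dot-product attention on token arrays (B, N, D); softmax over the
# key axis; temperature sqrt(D).
ag_attention <- function(q, k, v) {
  q <- as_node(q); k <- as_node(k); v <- as_node(v)
  check_same_shape(q$value, k$value, "q and k")
  check_same_shape(q$value, v$value, "q and v")
  d <- dim(q$value)
  B <- d[1]; N <- d[2]; D <- d[3]
  scale <- 1 / sqrt(D)
  out <- array(0, d)
  A_list <- vector("list", B)
  for (b in seq_len(B)) {
    Q <- matrix(q$value[b, , ], N, D)
    K <- matrix(k$value[b, , ], N, D)
    V <- matrix(v$value[b, , ], N, D)
    A <- row_softmax(Q %*% t(K) * scale)
    A_list[[b]] <- A
    out[b, , ] <- A %*% V
  }
  qv <- q$value; kv <- k$value; vv <- v$value
  ag_node(out, list(q, k, v), function(g) {
    gq <- array(0, d); gk <- array(0, d); gv <- array(0, d)
    for (b in seq_len(B)) {
      Gb <- matrix(g[b, , ], N, D)
      Q <- matrix(qv[b, , ], N, D)
      K <- matrix(kv[b, , ], N, D)
      V <- matrix(vv[b, , ], N, D)
      A <- A_list[[b]]
      gv[b, , ] <- t(A) %*% Gb
      gA <- Gb %*% t(V)
      gS <- A * (gA - rowSums(gA * A))
      gq[b, , ] <- (gS %*% K) * scale
      gk[b, , ] <- (t(gS) %*% Q) * scale
    }
    list(gq, gk, gv)
  })
}

## ---- concatenation / slicing ----

ag_concat_c <- function(xs) {
  xs <- lapply(xs, as_node)
  dims <- lapply(xs, function(x) dim(x$value))
  for (dd in dims[-1])
    if (!identical(dd[c(1, 3, 4)], dims[[1]][c(1, 3, 4)]))
      stopf("channel concat needs matching batch/spatial dims: %s vs %s",
            paste(dims[[1]], collapse = "x"), paste(dd, collapse = "x"))
  cs <- vapply(dims, `[`, integer(1), 2L)
  d <- dims[[1]]
  out <- array(0, c(d[1], sum(cs), d[3], d[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, at + seq_len(cs[i]), , ] <- xs[[i]]$value
    at <- at + cs[i]
  }
  ag_node(out, xs, function(g) {
    pos <- 0L
    grads <- vector("list", length(xs))
    for (i in seq_along(xs)) {
      grads[[i]] <- g[, pos + seq_len(cs[i]), , , drop = FALSE]
      pos <- pos + cs[i]
    }
    grads
  })
}

ag_slice_c <- function(x, from, len) {
  x <- as_node(x)
  d <- dim(x$value)
  y <- x$value[, from - 1L + seq_len(len), , , drop = FALSE]
  ag_node(y, list(x), function(g) {
    gx <- array(0, d)
    gx[, from - 1L + seq_len(len), , ] <- g
    list(gx)
  })
}

# Concatenate along the third (profile-length) axis; last axis must agree.
ag_concat_3 <- function(xs) {
  xs <- lapply(xs, as_node)
  dims <- lapply(xs, function(x) dim(x$value))
  ls <- vapply(dims, `[`, integer(1), 3L)
  d <- dims[[1]]
  out <- array(0, c(d[1], d[2], sum(ls), d[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , at + seq_len(ls[i]), ] <- xs[[i]]$value
    at <- at + ls[i]
  }
  ag_node(out, xs, function(g) {
    pos <- 0L
    grads <- vector("list", length(xs))
    for (i in seq_along(xs)) {
      grads[[i]] <- g[, , pos + seq_len(ls[i]), , drop = FALSE]
      pos <- pos + ls[i]
    }
    grads
  })
}

ag_slice_3 <- function(x, from, len) {
  x <- as_node(x)
  d <- dim(x$value)
  y <- x$value[, , from - 1L + seq_len(len), , drop = FALSE]
  ag_node(y, list(x), function(g) {
    gx <- array(0, d)
    gx[, , from - 1L + seq_len(len), ] <- g
    list(gx)
  })
}

# Swap the last two array dims (height profile <-> width-profile layout).
ag_trans_last2 <- function(x) {
  x <- as_node(x)
  ag_node(aperm(x$value, c(1, 2, 4, 3)), list(x),
          function(g) list(aperm(g, c(1, 2, 4, 3))))
}

## ---- broadcast products ----

# Multiply a full grid by a one-channel weight map (B, 1, H, W).
ag_mul_map <- function(x, m) {
  x <- as_node(x); m <- as_node(m)
  dx <- dim(x$value); dm <- dim(m$value)
  if (dm[2] != 1L) stopf("weight map must have one channel, got %d", dm[2])
  if (!identical(dx[c(1, 3, 4)], dm[c(1, 3, 4)]))
    stopf("weight map spatial dims %s do not match grid %s",
          fmt_dim(m$value), fmt_dim(x$value))
  C <- dx[2]
  mexp <- array(m$value[, rep(1L, C), , , drop = FALSE], dx)
  xv <- x$value
  ag_node(xv * mexp, list(x, m), function(g) {
    gm <- g * xv
    gm <- array(rowSums(matrix(aperm(gm, c(1, 3, 4, 2)), ncol = C)),
                c(dx[1], 1L, dx[3], dx[4]))
    list(g * mexp, gm)
  })
}

# Multiply a grid (B, C, H, W) by a width profile (B, C, W, 1): each column w
# of the grid is scaled by the profile entry at w.
ag_mul_wprofile <- function(x, p) {
  x <- as_node(x); p <- as_node(p)
  dx <- dim(x$value); dp <- dim(p$value)
  if (dp[4] != 1L || dp[3] != dx[4] || dp[2] != dx[2] || dp[1] != dx[1])
    stopf("width profile %s incompatible with grid %s",
          fmt_dim(p$value), fmt_dim(x$value))
  B <- dx[1]; C <- dx[2]; H <- dx[3]; W <- dx[4]
  pe <- aperm(array(p$value, c(B, C, W, H)), c(1, 2, 4, 3))  # (B,C,H,W)
  xv <- x$value
  ag_node(xv * pe, list(x, p), function(g) {
    gp <- apply(g * xv, c(1, 2, 4), sum)      # (B, C, W)
    list(g * pe, array(gp, c(B, C, W, 1)))
  })
}

# Multiply a grid (B, C, H, W) by a height profile (B, C, 1, H).
ag_mul_hprofile <- function(x, p) {
  x <- as_node(x); p <- as_node(p)
  dx <- dim(x$value); dp <- dim(p$value)
  if (dp[3] != 1L || dp[4] != dx[3] || dp[2] != dx[2] || dp[1] != dx[1])
    stopf("height profile %s incompatible with grid %s",
          fmt_dim(p$value), fmt_dim(x$value))
  B <- dx[1]; C <- dx[2]; H <- dx[3]; W <- dx[4]
  pe <- array(p$value, c(B, C, H))            # (B, C, H)
  pe <- array(pe, c(B, C, H, W))              # broadcast over W
  xv <- x$value
  ag_node(xv * pe, list(x, p), function(g) {
    gp <- apply(g * xv, c(1, 2, 3), sum)      # (B, C, H)
    list(g * pe, array(gp, c(B, C, 1, H)))
  })
}

## ---- pooling / resampling ----

# Directional max pooling. keep = "w": collapse height -> (B, C, W, 1);
# keep = "h": collapse width -> (B, C, 1, H).
ag_maxpool_axis <- function(x, keep = c("w", "h")) {
  keep <- match.arg(keep)
  x <- as_node(x)
  d <- dim(x$value)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  if (keep == "w") {
    am <- apply(x$value, c(1, 2, 4), which.max)           # (B, C, W)
    y <- apply(x$value, c(1, 2, 4), max)
    node <- ag_node(array(y, c(B, C, W, 1)), list(x), function(g) {
      gx <- array(0, d)
      gflat <- array(g, c(B, C, W))
      for (b in seq_len(B)) for (cc in seq_len(C)) for (w in seq_len(W))
        gx[b, cc, am[b, cc, w], w] <- gx[b, cc, am[b, cc, w], w] + gflat[b, cc, w]
      list(gx)
    })
  } else {
    am <- apply(x$value, c(1, 2, 3), which.max)           # (B, C, H)
    y <- apply(x$value, c(1, 2, 3), max)
    node <- ag_node(array(y, c(B, C, 1, H)), list(x), function(g) {
      gx <- array(0, d)
      gflat <- array(g, c(B, C, H))
      for (b in seq_len(B)) for (cc in seq_len(C)) for (h in seq_len(H))
        gx[b, cc, h, am[b, cc, h]] <- gx[b, cc, h, am[b, cc, h]] + gflat[b, cc, h]
      list(gx)
    })
  }
  node
}

# Same-size k x k max pooling (stride 1), used by the SPP-style neck block.
ag_maxpool2d <- function(x, k) {
  x <- as_node(x)
  r <- cpp_maxpool2d(x$value, as.integer(k))
  am <- r$argmax
  ag_node(r$y, list(x), function(g) list(cpp_maxpool2d_backward(am, g)))
}

# Nearest-neighbour x2 upsampling.
ag_upsample2 <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  y <- x$value[, , rep(seq_len(H), each = 2), rep(seq_len(W), each = 2), drop = FALSE]
  ag_node(y, list(x), function(g) {
    dim(g) <- c(B, C, 2, H, 2, W)
    list(array(colSums(aperm(g, c(3, 5, 1, 2, 4, 6)), dims = 2), c(B, C, H, W)))
  })
}

## ---- reductions / losses ----

ag_mean <- function(x) {
  x <- as_node(x)
  n <- length(x$value)
  ag_node(array(mean(x$value), 1L), list(x),
          function(g) list(array(as.numeric(g) / n, dim(x$value))))
}

# Binary cross-entropy with logits, averaged over weighted cells.
# `target` and `weight` are plain arrays shaped like x.
ag_bce_logits <- function(x, target, weight = NULL) {
  x <- as_node(x)
  z <- x$value
  if (is.null(weight)) weight <- array(1, dim(z))
  wsum <- sum(weight)
  if (wsum <= 0) return(ag_node(array(0, 1L), list(x), function(g) list(array(0, dim(z)))))
  # stable: max(z,0) - z*t + log(1 + exp(-|z|))
  lo <- pmax(z, 0) - z * target + log1p(exp(-abs(z)))
  val <- sum(lo * weight) / wsum
  ag_node(array(val, 1L), list(x), function(g) {
    s <- 1 / (1 + exp(-z))
    list((s - target) * weight * as.numeric(g) / wsum)
  })
}
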