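# Adam with decoupled weight decay and the warm-up / cosine-decay learning
# rate schedule.

adam_new <- function(params, lr = 0.01, beta1 = 0.975, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 5e-4) {
  list(params = params, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay, t = 0L,
       m = lapply(params, function(p) array(0, dim(p$value) %||% length(p$value))),
       v = lapply(params, function(p) array(0, dim(p$value) %||% length(p$value))))
}

# Global-norm gradient clipping, applied before every optimiser step.
clip_grad_norm <- function(params, max_norm = 5) {
  total <- 0
  for (p in params) if (!is.null(p$grad)) total <- total + sum(p$grad^2)
  total <- sqrt(total)
  if (is.finite(total) && total > max_norm) {
    sc <- max_norm / total
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * sc
  }
  total
}

adam_step <- function(opt, lr = opt$lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (opt$weight_decay > 0) p$value <- p$value * (1 - lr * opt$weight_decay)
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g^2
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}

# Linear warm-up from `warmup_factor` x base over `warmup` epochs, then
# cosine decay to 10% of base by the final epoch. `epoch` is zero-based.
lr_at_epoch <- function(epoch, total_epochs, base_lr = 0.01,
                        warmup = 3, warmup_factor = 0.1) {
  if (warmup > 0 && epoch < warmup) {
    frac <- (epoch + 1) / warmup
    return(base_lr * (warmup_factor + (1 - warmup_factor) * frac))
  }
  span <- max(1, total_epochs - warmup)
  prog <- min(1, (epoch - warmup) / span)
  base_lr * (0.1 + 0.9 * 0.5 * (1 + cos(pi * prog)))
}
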