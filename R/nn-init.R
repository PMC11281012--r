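# Parameter construction for the fusion blocks and the backbone.
#
# A "conv" parameter set is list(W, b) with W shaped (out, in, k, k); a
# "layer norm" set is list(gamma, beta) of length C. Module constructors
# return nested named lists of autograd parameter leaves; the functional
# block API also accepts the same structure built from plain arrays.

init_conv <- function(out_c, in_c, k, mode = c("he", "zero", "dirac"),
                      bias = 0) {
  mode <- match.arg(mode)
  W <- array(0, c(out_c, in_c, k, k))
  if (mode == "he") {
    W[] <- rnorm(length(W), sd = sqrt(2 / (in_c * k * k)))
  } else if (mode == "dirac") {
    if (out_c != in_c) stopf("dirac init needs out == in channels")
    ctr <- (k + 1L) %/% 2L
    for (i in seq_len(out_c)) W[i, i, ctr, ctr] <- 1
  }
  list(W = ag_param(W), b = ag_param(rep(as.numeric(bias), out_c)))
}

init_ln <- function(C) {
  list(gamma = ag_param(rep(1, C)), beta = ag_param(rep(0, C)))
}

# Recursively collect autograd parameter leaves from a nested weight list.
collect_params <- function(w) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "ag_node")) {
      if (x$is_param) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(w)
  out
}

# Count of scalar parameters held in a nested weight list.
n_param_values <- function(w) {
  sum(vapply(collect_params(w), function(p) length(p$value), numeric(1)))
}

# Snapshot / restore parameter values (used by checkpoints).
params_state <- function(w) lapply(collect_params(w), function(p) p$value)

params_load <- function(w, state) {
  ps <- collect_params(w)
  if (length(ps) != length(state))
    stopf("checkpoint has %d parameter arrays, model expects %d",
          length(state), length(ps))
  for (i in seq_along(ps)) {
    if (!identical(dim(ps[[i]]$value) %||% length(ps[[i]]$value),
                   dim(state[[i]]) %||% length(state[[i]])))
      stopf("parameter %d shape mismatch in checkpoint", i)
    ps[[i]]$value <- state[[i]]
  }
  invisible(w)
}
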