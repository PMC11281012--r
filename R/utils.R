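stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

fmt_dim <- function(x) paste(dim(x), collapse = "x")

#' Validate a feature grid
#'
#' Feature grids are plain numeric 4-d arrays indexed
#' `(batch, channel, height, width)`; every block in the package consumes and
#' produces them.
#'
#' @param x object to validate.
#' @param name label used in error messages.
#' @return `x`, invisibly, if valid.
#' @export
check_feature_grid <- function(x, name = "x") {
  if (!is.array(x) || length(dim(x)) != 4L)
    stopf("%s must be a 4-d (batch, channel, height, width) array", name)
  if (!is.numeric(x))
    stopf("%s must be numeric", name)
  invisible(x)
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stopf("%s must share one shape: got %s vs %s", what, fmt_dim(a), fmt_dim(b))
  invisible(TRUE)
}

# Deterministic child seed derivation, kept below 2^31.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(salt)) %% 2147483399)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
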