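# Scaffold construction, forward contracts, parameter counting, and
# checkpointing.

small_cfg <- function(...) {
  model_config(stage_channels = c(4L, 6L, 8L), num_classes = 2L,
               input_size = c(64L, 64L), ...)
}

test_that("model_config validates its invariants", {
  expect_error(model_config(stage_channels = c(8, 8, 16)), "strictly increasing")
  expect_error(model_config(stage_channels = c(16, 8)), "length 3")
  expect_error(model_config(num_classes = 0), "num_classes")
  expect_error(model_config(input_size = c(100, 100)), "divisible")
  expect_error(model_config(modalities = 4), "modalities")
  cfg <- model_config(scale = "s")
  expect_true(all(diff(cfg$stage_channels) > 0))
  expect_true(all(cfg$stage_channels %% 2 == 0))
})

test_that("construction is seeded and deterministic", {
  cfg <- small_cfg()
  m1 <- build_model(cfg, seed = 5)
  m2 <- build_model(cfg, seed = 5)
  s1 <- rgbdet:::params_state(rgbdet:::model_weight_lists(m1))
  s2 <- rgbdet:::params_state(rgbdet:::model_weight_lists(m2))
  expect_identical(s1, s2)
  m3 <- build_model(cfg, seed = 6)
  s3 <- rgbdet:::params_state(rgbdet:::model_weight_lists(m3))
  expect_false(identical(s1, s3))
})

test_that("forward emits three per-scale grids with 5 + classes channels", {
  set.seed(31)
  model <- build_model(small_cfg(), seed = 1)
  rgb <- rand_grid(2, 3, 64, 64, sd = 0.5)
  dep <- rand_grid(2, 1, 64, 64, sd = 0.5)
  out <- forward_model(model, rgb, dep)
  expect_length(out, 3)
  expect_identical(dim(out[[1]]), c(2L, 7L, 8L, 8L))
  expect_identical(dim(out[[2]]), c(2L, 7L, 4L, 4L))
  expect_identical(dim(out[[3]]), c(2L, 7L, 2L, 2L))
  expect_identical(out, forward_model(model, rgb, dep))  # frozen-weight determinism
  expect_error(forward_model(model, rgb, rand_grid(2, 1, 32, 32)),
               "share batch and spatial size")
})

test_that("the concatenation baseline (blocks disabled) depends on RGB alone
           once the depth stream is silenced", {
  set.seed(32)
  cfg <- small_cfg(use_lgem = FALSE, use_rfam = FALSE)
  model <- build_model(cfg, seed = 2)
  expect_null(model$lgem); expect_null(model$rfam)
  # zero every parameter of the depth stream
  for (p in rgbdet:::collect_params(model$streams$depth)) p$value[] <- 0
  rgb <- rand_grid(1, 3, 64, 64, sd = 0.5)
  d1 <- rand_grid(1, 1, 64, 64); d2 <- rand_grid(1, 1, 64, 64)
  expect_equal(forward_model(model, rgb, d1), forward_model(model, rgb, d2))
})

test_that("tri-modal and auxiliary variants build and run", {
  set.seed(33)
  m3 <- build_model(small_cfg(modalities = 3L), seed = 3)
  out <- forward_model(m3, rand_grid(1, 3, 64, 64), rand_grid(1, 1, 64, 64),
                       rand_grid(1, 1, 64, 64))
  expect_length(out, 3)
  expect_error(forward_model(m3, rand_grid(1, 3, 64, 64),
                             rand_grid(1, 1, 64, 64)), "ir input")
  ma <- build_model(small_cfg(use_aux = TRUE), seed = 4)
  tr <- rgbdet:::forward_core(ma, rand_grid(1, 3, 64, 64),
                              rand_grid(1, 1, 64, 64), train = TRUE)
  expect_length(tr$aux, 3)
  # aux branch is training-only: inference path ignores it
  inf <- rgbdet:::forward_core(ma, rand_grid(1, 3, 64, 64),
                               rand_grid(1, 1, 64, 64), train = FALSE)
  expect_null(inf$aux)
  expect_gt(count_params(ma), count_params(build_model(small_cfg(), seed = 4)))
})

test_that("the closed-form parameter count equals exhaustive enumeration", {
  # single conv / fc layer fixtures
  conv <- rgbdet:::init_conv(16L, 3L, 3L)
  expect_identical(count_params(list(conv)), 448L)     # (9*3 + 1) * 16
  expect_identical(count_params_direct(list(conv)), 448L)
  fc <- list(W = rgbdet:::ag_param(matrix(0, 5, 10)),
             b = rgbdet:::ag_param(numeric(5)))
  expect_identical(count_params(list(fc)), 55L)        # (10 + 1) * 5
  expect_identical(count_params(list()), 0L)
  set.seed(34)
  for (i in 1:6) {
    cfg <- model_config(
      stage_channels = sort(sample(seq(4L, 24L, by = 2L), 3L)),
      stage_depth = sample(1:2, 1), num_classes = sample(1:5, 1),
      modalities = sample(c(2L, 3L), 1), scale = sample(c("s", "m", "l"), 1),
      use_lgem = sample(c(TRUE, FALSE), 1), use_rfam = sample(c(TRUE, FALSE), 1),
      use_aux = sample(c(TRUE, FALSE), 1))
    m <- build_model(cfg, seed = i)
    expect_identical(count_params(m), count_params_direct(m))
  }
})

test_that("parameter count grows with the scale preset", {
  ns <- c(s = 0L, m = 0L, l = 0L)
  for (sc in names(ns))
    ns[sc] <- count_params(build_model(model_config(scale = sc), seed = 1))
  expect_true(ns[["s"]] < ns[["m"]] && ns[["m"]] < ns[["l"]])
})

test_that("checkpoints round-trip the model bit-exactly", {
  set.seed(35)
  model <- build_model(small_cfg(), seed = 7)
  rgb <- rand_grid(1, 3, 64, 64, sd = 0.5); dep <- rand_grid(1, 1, 64, 64, sd = 0.5)
  ref <- forward_model(model, rgb, dep)
  ck <- file.path(tempdir(), "bb-test.ckpt")
  save_checkpoint(model, ck)
  restored <- load_checkpoint(ck)
  expect_identical(forward_model(restored, rgb, dep), ref)
  unlink(ck)
})

test_that("one training step sends gradients to every learnable parameter", {
  set.seed(36)
  model <- build_model(model_config(stage_channels = c(4, 6, 8),
                                    num_classes = 2, input_size = c(32, 32),
                                    use_aux = TRUE), seed = 9)
  params <- rgbdet:::model_params(model)
  rgbdet:::ag_zero_grad(params)
  out <- rgbdet:::forward_core(model, rand_grid(1, 3, 32, 32, sd = 0.5),
                               rand_grid(1, 1, 32, 32, sd = 0.5), train = TRUE)
  labels <- list(tibble::tibble(class_id = 0L, xc = 0.5, yc = 0.5,
                                w = 0.6, h = 0.6))
  ls <- rgbdet:::detection_loss(out, labels, c(32, 32), 2L)
  rgbdet:::ag_backward(ls$total)
  expect_true(all(vapply(params, function(p) !is.null(p$grad), logical(1))))
})

test_that("measure_speed reports positive milliseconds per sample", {
  model <- build_model(small_cfg(), seed = 8)
  pairs <- list(list(rgb = rand_grid(1, 3, 64, 64), depth = rand_grid(1, 1, 64, 64)))
  sp <- measure_speed(model, pairs)
  expect_true(is.finite(sp) && sp > 0)
  expect_error(measure_speed(model, list()), "at least one")
})
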