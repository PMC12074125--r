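# Network assembly: encoder/decoder blocks, full model, parameter counting.

test_that("encoder block halves resolution and keeps the skip", {
  set.seed(20)
  enc <- nn_encoder_block(3L, 8L)
  x <- array(runif(16 * 12 * 3), c(16, 12, 3, 1))
  r <- enc$fw(x)
  expect_identical(dim(r$skip), c(16L, 12L, 8L, 1L))
  expect_identical(dim(r$pooled), c(8L, 6L, 8L, 1L))

  zero_biases(enc)
  z <- array(0, c(8, 8, 3, 1))
  rz <- enc$fw(z)
  expect_equal(rz$skip, array(0, c(8, 8, 8, 1)))
  expect_equal(rz$pooled, array(0, c(4, 4, 8, 1)))

  expect_error(enc$fw(array(0, c(1, 8, 3, 1))), "pooling")
})

test_that("decoder block fuses to the expected shape with and without EF", {
  set.seed(21)
  for (use_ef in c(TRUE, FALSE)) {
    dec <- nn_decoder_block(8L, 4L, 4L, use_ef = use_ef, groups = 2L)
    g <- rand_map(4, 4, 8)
    skip <- rand_map(8, 8, 4)
    y <- dec$fw(g, skip)
    expect_identical(dim(y), c(8L, 8L, 4L, 1L))
  }
  dec <- nn_decoder_block(8L, 4L, 4L, use_ef = FALSE)
  expect_error(dec$fw(rand_map(4, 4, 8), rand_map(16, 16, 4)), "resolution")
})

test_that("the assembled model maps images to probabilities of the same size", {
  set.seed(22)
  cfg <- network_config(base_width = 8L, depth = 3L, num_heads = 4L, groups = 4L)
  model <- build_model(cfg)
  x <- array(runif(16 * 24 * 3 * 2), c(16, 24, 3, 2))
  p <- model_predict(model, x)
  expect_identical(dim(p), c(16L, 24L, 1L, 2L))
  expect_true(all(p > 0 & p < 1))

  expect_error(model$fw(array(0, c(12, 16, 3, 1))), "divisible")
  expect_error(model$fw(array(0, c(16, 16, 4, 1))), "channels")
  expect_error(network_config(base_width = 64L, num_heads = 7L), "divide")
})

test_that("two forward passes with identical weights agree bitwise", {
  set.seed(23)
  model <- build_model(network_config(base_width = 8L, depth = 2L,
                                      num_heads = 4L, groups = 4L))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  expect_identical(model_predict(model, x), model_predict(model, x))
})

test_that("parameter counting is exact and ablation-monotone", {
  conv <- nn_conv2d(3L, 64L)
  expect_identical(count_parameters(conv)$total, 3 * 64 * 9 + 64)
  expect_identical(count_parameters(axunet:::new_module("empty"))$total, 0)

  base <- list(base_width = 16L, depth = 4L, num_heads = 8L)
  n_plain <- count_parameters(build_model(do.call(network_config,
    c(base, list(use_mdmsc = FALSE, use_ef = FALSE)))))$total
  n_ef <- count_parameters(build_model(do.call(network_config,
    c(base, list(use_mdmsc = FALSE, use_ef = TRUE)))))$total
  n_full <- count_parameters(build_model(do.call(network_config, base)))$total
  expect_lt(n_plain, n_ef)
  expect_lt(n_ef, n_full)

  s <- count_parameters(build_model(do.call(network_config, base)))
  expect_identical(sum(s$breakdown$count), s$total)
})

test_that("gradient reaches every trainable parameter", {
  set.seed(24)
  model <- build_model(network_config(base_width = 8L, depth = 2L,
                                      num_heads = 4L, groups = 4L))
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- array((runif(16 * 16 * 2) > 0.5) * 1, c(16, 16, 1, 2))
  z <- model$fw(x, training = TRUE)
  l <- axunet:::seg_loss(z, y)
  axunet:::zero_grads(model)
  model$bw(l$dz)
  dead <- vapply(axunet:::collect_parameters(model), function(e)
    all(e$env$grads[[e$name]] == 0), logical(1))
  expect_false(any(dead))
})
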