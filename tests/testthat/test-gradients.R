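# Backward passes against central finite differences on tiny maps.

fd_input_grad <- function(fwd, x, dy, eps = 1e-6) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (sum(fwd(xp) * dy) - sum(fwd(xm) * dy)) / (2 * eps)
  }
  g
}

expect_layer_grads <- function(layer, x, tol = 1e-6) {
  y <- layer$fw(x, training = TRUE)
  set.seed(1234)
  dy <- array(rnorm(length(y)), dim(y))
  axunet:::zero_grads(layer)
  dx <- layer$bw(dy)
  fwd <- function(xx) layer$fw(xx, training = TRUE)
  expect_lt(max(abs(dx - fd_input_grad(fwd, x, dy))), tol)
  # parameters: spot-check every tensor at its first element
  layer$fw(x, training = TRUE)
  axunet:::zero_grads(layer)
  layer$bw(dy)
  for (e in axunet:::collect_parameters(layer)) {
    p <- e$env$params[[e$name]]
    ag <- e$env$grads[[e$name]][1]
    e$env$params[[e$name]][1] <- p[1] + 1e-6
    fp <- sum(layer$fw(x, training = TRUE) * dy)
    e$env$params[[e$name]][1] <- p[1] - 1e-6
    fm <- sum(layer$fw(x, training = TRUE) * dy)
    e$env$params[[e$name]][1] <- p[1]
    expect_lt(abs(ag - (fp - fm) / 2e-6), tol)
  }
}

test_that("layer backward passes match central finite differences", {
  set.seed(70)
  x <- rand_map(5, 6, 4, 2)
  expect_layer_grads(nn_conv2d(4L, 6L), x)
  expect_layer_grads(nn_conv2d(4L, 4L, groups = 2L), x)
  expect_layer_grads(axunet:::nn_dwconv1d(4L, 5L, "y"), x)
  expect_layer_grads(axunet:::nn_layernorm(4L), x)
  expect_layer_grads(axunet:::nn_batchnorm(4L), x)
  expect_layer_grads(axunet:::nn_maxpool2(), rand_map(6, 6, 3))
  expect_layer_grads(axunet:::nn_upsample2(), rand_map(4, 5, 3))
  expect_layer_grads(nn_mdmsc(4L, 2L, kernels = c(3L, 5L)), rand_map(4, 5, 4))
  expect_layer_grads(nn_ec(4L), x)
})

test_that("attention backward matches finite differences in all three roles", {
  set.seed(71)
  d <- c(3L, 4L, 2L, 1L)
  q <- array(rnorm(prod(d)), d); k <- array(rnorm(prod(d)), d)
  v <- array(rnorm(prod(d)), d)
  for (ax in c(0L, 1L)) {
    y <- axunet:::cpp_axattn_fw(q, k, v, d, ax, 0.7)
    dy <- array(rnorm(length(y)), d)
    g <- axunet:::cpp_axattn_bw(q, k, v, dy, d, ax, 0.7)
    fq <- fd_input_grad(function(z) axunet:::cpp_axattn_fw(z, k, v, d, ax, 0.7), q, dy)
    fk <- fd_input_grad(function(z) axunet:::cpp_axattn_fw(q, z, v, d, ax, 0.7), k, dy)
    fv <- fd_input_grad(function(z) axunet:::cpp_axattn_fw(q, k, z, d, ax, 0.7), v, dy)
    expect_lt(max(abs(g$dq - fq)), 1e-6)
    expect_lt(max(abs(g$dk - fk)), 1e-6)
    expect_lt(max(abs(g$dv - fv)), 1e-6)
  }
})
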