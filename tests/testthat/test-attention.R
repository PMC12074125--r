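# Multi-head multi-scale cross-axis attention block.

test_that("layer normalization centres and scales channel vectors", {
  # constant map: mean removed, 0/sqrt(eps) -> exactly 0
  x <- array(5, c(3, 4, 6))
  expect_equal(layer_normalize(x), array(0, c(3, 4, 6)))

  # hand evaluation: channels (1, 3) -> (-1, 1) as eps -> 0
  x <- array(c(1, 3), c(1, 1, 2))
  y <- layer_normalize(x, eps = 1e-12)
  expect_equal(as.numeric(y), c(-1, 1), tolerance = 1e-5)

  # shape contract and affine parameters
  set.seed(1)
  x <- array(rnorm(60), c(3, 5, 4))
  g <- c(2, 1, 0.5, 3); b <- c(1, -1, 0, 2)
  y <- layer_normalize(x, gain = g, bias = b)
  expect_identical(dim(y), dim(x))
  base <- layer_normalize(x)
  expect_equal(y, sweep(sweep(base, 3, g, `*`), 3, b, `+`))

  expect_error(layer_normalize(array(numeric(0), c(2, 2, 0))))
})

test_that("depthwise strip convolution matches the direct 1-D oracle", {
  v <- c(0, 0, 1, 0, 0)
  layer <- axunet:::nn_dwconv1d(1L, 3L, "x")
  layer$params$W[] <- 1   # kernel (1,1,1)
  layer$params$b[] <- 0
  x <- array(v, c(1, 5, 1, 1))
  expect_equal(as.numeric(layer$fw(x)), c(0, 1, 1, 1, 0))

  # random kernels along both axes against the padded-loop oracle
  set.seed(11)
  for (axis in c("x", "y")) {
    k <- 5L
    layer <- axunet:::nn_dwconv1d(3L, k, axis)
    x <- rand_map(7, 9, 3)
    y <- layer$fw(x)
    for (c in 1:3) {
      kern <- as.numeric(layer$params$W[, , 1, c])
      if (axis == "x") {
        for (h in 1:7)
          expect_equal(y[h, , c, 1],
                       oracle_conv1d(x[h, , c, 1], kern) + layer$params$b[c],
                       tolerance = 1e-12)
      } else {
        for (w in 1:9)
          expect_equal(y[, w, c, 1],
                       oracle_conv1d(x[, w, c, 1], kern) + layer$params$b[c],
                       tolerance = 1e-12)
      }
    }
  }
  expect_error(axunet:::nn_dwconv1d(3L, 4L, "x"), "odd")
})

test_that("multi-scale branch preserves shape and propagates zeros", {
  set.seed(2)
  br <- nn_msc_branch(8L, "x")
  x <- rand_map(6, 10, 8)
  expect_identical(dim(br$fw(x)), dim(x))

  zero_biases(br)
  z <- array(0, c(4, 5, 8, 1))
  expect_equal(br$fw(z), z)

  expect_error(nn_msc_branch(8L, "x", kernels = c(6, 11)), "odd")
})

test_that("cross-axis attention follows the softmax contract", {
  set.seed(3)
  # single-token sequences: output equals the value map
  q <- rand_map(5, 1, 4); k <- rand_map(5, 1, 4); v <- rand_map(5, 1, 4)
  expect_equal(cross_axis_attention(q, k, v, "x"), v)

  # constant Q and K: uniform weights -> row means of V
  H <- 4; W <- 6; C <- 3
  q <- array(1, c(H, W, C)); k <- array(2, c(H, W, C))
  v <- array(rnorm(H * W * C), c(H, W, C))
  y <- cross_axis_attention(q, k, v, "x")
  for (h in 1:H) for (c in 1:C)
    expect_equal(y[h, , c], rep(mean(v[h, , c]), W), tolerance = 1e-12)

  # weight vectors sum to 1
  q <- rand_map(4, 6, 8); k <- rand_map(4, 6, 8); v <- rand_map(4, 6, 8)
  r <- cross_axis_attention(q, k, v, "x", return_weights = TRUE)
  sums <- apply(r$weights, c(1, 3, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-6))

  expect_error(cross_axis_attention(rand_map(3, 3, 2), rand_map(3, 3, 2),
                                    rand_map(3, 4, 2), "x"), "shape")
})

test_that("cross-axis attention matches the naive triple-loop oracle", {
  set.seed(4)
  for (rep in 1:3) {
    H <- sample(1:4, 1); W <- sample(1:4, 1); C <- sample(1:4, 1)
    q <- array(rnorm(H * W * C), c(H, W, C))
    k <- array(rnorm(H * W * C), c(H, W, C))
    v <- array(rnorm(H * W * C), c(H, W, C))
    for (axis in c("x", "y")) {
      sc <- 1 / sqrt(C)
      expect_equal(cross_axis_attention(q, k, v, axis),
                   oracle_axattn(q, k, v, axis, sc), tolerance = 1e-6)
    }
  }
})

test_that("single-head attention respects zero projections and shape", {
  set.seed(5)
  head <- nn_mca_head(8L, proj_init = "zeros")
  x <- rand_map(5, 7, 8)
  expect_equal(head$fw(x), array(0, dim(x)))

  head2 <- nn_mca_head(8L)
  expect_identical(dim(head2$fw(x)), dim(x))

  zero_biases(head2)
  z <- array(0, c(4, 4, 8, 1))
  expect_equal(head2$fw(z), z)
})

test_that("the multi-head block is residual, shape-preserving and validated", {
  set.seed(6)
  blk <- nn_mdmsc(16L, num_heads = 4L)
  x <- rand_map(6, 8, 16, 2)
  expect_identical(dim(blk$fw(x)), dim(x))

  blk0 <- nn_mdmsc(16L, num_heads = 4L, proj_init = "zeros")
  expect_equal(blk0$fw(x), x)

  err <- expect_error(nn_mdmsc(64L, num_heads = 7L))
  expect_match(conditionMessage(err), "7")
  expect_match(conditionMessage(err), "64")
})

test_that("permuting head groups with their parameters permutes the output", {
  set.seed(7)
  heads <- 4L; d <- 3L; C <- heads * d
  b1 <- nn_mdmsc(C, num_heads = heads, kernels = c(3L, 5L))
  x <- rand_map(5, 6, C)
  y1 <- b1$fw(x)

  perm <- c(3L, 1L, 4L, 2L)   # head i of b2 = head perm[i] of b1
  b2 <- nn_mdmsc(C, num_heads = heads, kernels = c(3L, 5L))
  sd1 <- axunet:::state_dict(b1)
  sd2 <- sd1
  for (i in seq_len(heads)) {
    from <- paste0("head", perm[i], "."); to <- paste0("head", i, ".")
    for (nm in names(sd1)[startsWith(names(sd1), from)])
      sd2[[sub(from, to, nm, fixed = TRUE)]] <- sd1[[nm]]
  }
  axunet:::load_state_dict(b2, sd2)

  slice <- function(a, i) a[, , ((i - 1) * d + 1):(i * d), , drop = FALSE]
  xp <- x
  for (i in seq_len(heads)) xp[, , ((i - 1) * d + 1):(i * d), ] <- slice(x, perm[i])
  y2 <- b2$fw(xp)
  for (i in seq_len(heads))
    expect_equal(slice(y2, i), slice(y1, perm[i]), tolerance = 1e-12)
})
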