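# Gated efficient feature fusion (EA gate + EC channel attention).

test_that("zero-initialized gate multiplies the skip by exactly 1.5", {
  set.seed(10)
  ea <- nn_ea(6L, 6L, groups = 2L)
  ea$children$psi$params$W[] <- 0
  ea$children$psi$params$b[] <- 0
  g <- rand_map(5, 5, 6); x <- rand_map(5, 5, 6)
  expect_equal(ea$fw(g, x, training = TRUE), 1.5 * x, tolerance = 1e-12)
})

test_that("EA output lies strictly between x and 2x for positive x", {
  set.seed(11)
  for (rep in 1:20) {
    ea <- nn_ea(4L, 4L, groups = 2L)
    g <- rand_map(4, 6, 4)
    x <- array(runif(4 * 6 * 4, 0.01, 1), c(4, 6, 4, 1))
    y <- ea$fw(g, x, training = TRUE)
    expect_true(all(y > x) && all(y < 2 * x))
  }
})

test_that("EA validates spatial agreement and group divisibility", {
  ea <- nn_ea(4L, 4L)
  expect_error(ea$fw(rand_map(8, 8, 4), rand_map(16, 16, 4)), "spatial")
  expect_error(nn_conv2d(6, 6, groups = 4), "divide")
})

test_that("EC channel attention obeys the residual floor and GAP oracle", {
  set.seed(12)
  ec <- nn_ec(5L)
  ec$children$proj$params$W[] <- 0
  ec$children$proj$params$b[] <- 0
  u <- rand_map(4, 7, 5, 2)
  expect_equal(ec$fw(u, training = TRUE), 1.5 * u, tolerance = 1e-12)

  # pooled descriptor equals a brute-force mean over positions
  ec2 <- nn_ec(5L)
  ec2$fw(u, training = TRUE)
  s <- ec2$cache$s
  for (n in 1:2) for (c in 1:5) {
    acc <- 0
    for (h in 1:4) for (w in 1:7) acc <- acc + u[h, w, c, n]
    expect_equal(s[1, 1, c, n], acc / 28, tolerance = 1e-6)
  }

  # constant channels pool to themselves
  uc <- array(rep(c(0.3, 1.7, -2), each = 12), c(3, 4, 3, 1))
  ec3 <- nn_ec(3L)
  ec3$fw(uc, training = TRUE)
  expect_equal(as.numeric(ec3$cache$s), c(0.3, 1.7, -2))

  # residual floor: nonnegative input, output >= input
  for (rep in 1:20) {
    ec4 <- nn_ec(4L)
    u4 <- array(runif(4 * 4 * 4), c(4, 4, 4, 1))
    expect_true(all(ec4$fw(u4, training = TRUE) >= u4))
  }
})

test_that("group convolution keeps channel groups independent", {
  set.seed(13)
  conv <- nn_conv2d(8L, 8L, groups = 4L, bias = FALSE)
  x <- rand_map(6, 6, 8)
  y1 <- conv$fw(x)
  x2 <- x
  x2[, , 3:4, ] <- 0     # zero out group 2's input channels
  y2 <- conv$fw(x2)
  expect_equal(y2[, , c(1:2, 5:8), , drop = FALSE],
               y1[, , c(1:2, 5:8), , drop = FALSE])
  expect_false(isTRUE(all.equal(y2[, , 3:4, , drop = FALSE],
                                y1[, , 3:4, , drop = FALSE])))
})

test_that("EF fusion concatenates, composes the zero-init gates, and drops zeros", {
  set.seed(14)
  ef <- nn_ef(6L, 4L, groups = 2L)
  g <- rand_map(8, 8, 6); x <- rand_map(8, 8, 4)
  y <- ef$fw(g, x, training = TRUE)
  expect_identical(dim(y), c(8L, 8L, 10L, 1L))

  # zero-initialize both sub-gates: output = 1.5 * concat(1.5 x, g)
  ef$children$ea$children$psi$params$W[] <- 0
  ef$children$ea$children$psi$params$b[] <- 0
  ef$children$ec$children$proj$params$W[] <- 0
  ef$children$ec$children$proj$params$b[] <- 0
  y <- ef$fw(g, x, training = TRUE)
  expect_equal(y, 1.5 * axunet:::abind4(1.5 * x, g), tolerance = 1e-12)

  # all-zero inputs with zero biases propagate zeros
  ef2 <- nn_ef(3L, 3L, groups = 1L)
  zero_biases(ef2)
  ef2$children$ea$children$psi$params$b[] <- 0
  z <- array(0, c(4, 4, 3, 1))
  expect_equal(ef2$fw(z, z, training = TRUE), array(0, c(4, 4, 6, 1)))
})

test_that("functional wrappers expose the gating bounds", {
  set.seed(15)
  x <- array(runif(6 * 6 * 4, 0.05, 1), c(6, 6, 4))
  g <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  y <- ea_gate(g, x, groups = 2L)
  expect_true(all(y > x) && all(y < 2 * x))
  u <- array(runif(6 * 6 * 4), c(6, 6, 4))
  expect_true(all(ec_attention(u) >= u))
  expect_identical(dim(ef_fuse(g, x, groups = 2L)), c(6L, 6L, 8L))
})
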