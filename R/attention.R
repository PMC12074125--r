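# Multi-head multi-scale cross-axis attention (MDMSC).
#
# The block splits the C input channels into `num_heads` contiguous groups.
# Each head normalizes its slice, runs two multi-scale strip-convolution
# branches (1-D depthwise convolutions of sizes 7/11/21 along x and along y,
# summed and projected by a 1x1 convolution), exchanges the two branches
# through scaled dot-product attention along each spatial axis, projects and
# sums the two attention outputs, and the head outputs are concatenated back
# in channel order. A residual connection adds the block input, so the block
# is shape-preserving and starts near the identity when the head projections
# are zero-initialized.

#' Layer normalization across channels
#'
#' Normalizes the channel vector at each spatial position to zero mean and
#' unit variance (with stabilizer `eps`), then applies a per-channel affine
#' transform.
#'
#' @param x feature map, dim `(H, W, C)` or `(H, W, C, N)`.
#' @param gain,bias per-channel affine parameters (default 1 and 0).
#' @param eps variance stabilizer.
#' @return an array with the same shape as `x`.
#' @export
layer_normalize <- function(x, gain = NULL, bias = NULL, eps = 1e-5) {
  x <- as_batch(x)
  C <- dim(x)[3]
  if (C < 1L) stop("cannot layer-normalize a map with no channels")
  if (is.null(gain)) gain <- rep(1, C)
  if (is.null(bias)) bias <- rep(0, C)
  y <- cpp_layernorm_fw(x, dim(x), as.numeric(gain), as.numeric(bias), eps)$y
  if (isTRUE(attr(x, "squeeze"))) dim(y) <- dim(y)[1:3]
  y
}

#' Scaled dot-product attention along one spatial axis
#'
#' For `axis = "x"` each of the H rows is an independent sequence of W tokens
#' of dimension C: attention weights are the row-wise softmax of
#' `scale * Q K'` and each output token is the weighted mean of the value
#' tokens in its row. For `axis = "y"` columns are the sequences.
#'
#' @param query,key,value feature maps of identical shape.
#' @param axis `"x"` (rows as sequences) or `"y"` (columns as sequences).
#' @param scale logit scale; defaults to `1/sqrt(C)`.
#' @param return_weights also return the attention weight tensor
#'   `(L, L, S, N)` (queries x keys x sequences x batch).
#' @return the attended map, or a list `(output, weights)`.
#' @export
cross_axis_attention <- function(query, key, value, axis = c("x", "y"),
                                 scale = NULL, return_weights = FALSE) {
  axis <- match.arg(axis)
  query <- as_batch(query); key <- as_batch(key); value <- as_batch(value)
  check_same_shape(query, key, value)
  if (is.null(scale)) scale <- 1 / sqrt(dim(query)[3])
  ax <- if (axis == "x") 0L else 1L
  y <- cpp_axattn_fw(query, key, value, dim(query), ax, scale)
  if (isTRUE(attr(query, "squeeze"))) dim(y) <- dim(y)[1:3]
  if (!return_weights) return(y)
  list(output = y,
       weights = cpp_axattn_weights(query, key, dim(as_batch(query)), ax, scale))
}

# Parameter-free attention as a layer (caches q/k/v for the backward pass).
nn_axattn <- function(axis, scale) {
  ax <- if (axis == "x") 0L else 1L
  self <- new_module("nn_axattn")
  self$fw <- function(q, k, v, training = FALSE) {
    self$cache <- list(q = q, k = k, v = v, d = dim(q))
    cpp_axattn_fw(q, k, v, dim(q), ax, scale)
  }
  self$bw <- function(dy) {
    cpp_axattn_bw(self$cache$q, self$cache$k, self$cache$v, dy,
                  self$cache$d, ax, scale)
  }
  self
}

#' Multi-scale strip-convolution branch
#'
#' `Conv1x1( sum_i DepthwiseConv1D_i( LayerNorm(x) ) )` with the 1-D
#' convolutions running along the chosen axis with 'same' padding.
#'
#' @param channels channel count of the maps the branch will process.
#' @param axis `"x"` or `"y"`.
#' @param kernels odd 1-D kernel sizes (default `c(7, 11, 21)`).
#' @return a layer module.
#' @export
nn_msc_branch <- function(channels, axis = c("x", "y"), kernels = c(7L, 11L, 21L)) {
  axis <- match.arg(axis)
  if (any(kernels %% 2L == 0L))
    stop("strip-convolution kernel sizes must be odd, got ",
         paste(kernels, collapse = ", "))
  self <- new_module("nn_msc_branch")
  dws <- lapply(kernels, function(k) nn_dwconv1d(channels, k, axis))
  names(dws) <- paste0("dw", kernels)
  self$children <- c(list(norm = nn_layernorm(channels)), dws,
                     list(proj = nn_conv2d(channels, channels, kernel = c(1L, 1L))))
  self$meta <- list(kernels = as.integer(kernels), axis = axis)
  self$fw <- function(x, training = FALSE) {
    t <- self$children$norm$fw(x, training)
    s <- 0
    for (k in self$meta$kernels) s <- s + self$children[[paste0("dw", k)]]$fw(t, training)
    self$children$proj$fw(s, training)
  }
  self$bw <- function(dy) {
    ds <- self$children$proj$bw(dy)
    dt <- 0
    for (k in self$meta$kernels) dt <- dt + self$children[[paste0("dw", k)]]$bw(ds)
    self$children$norm$bw(dt)
  }
  self
}

#' Single-head multi-scale cross-axis attention
#'
#' One head of the MDMSC block, operating on the per-head channel slice:
#' branches `Fx` (along x) and `Fy` (along y), then
#' `Ft = attend_x(Q = Fy, K = Fx, V = Fx)`,
#' `Fb = attend_y(Q = Fx, K = Fy, V = Fy)`, and the output
#' `Conv1x1(Ft) + Conv1x1(Fb)`.
#'
#' @param channels per-head channel count.
#' @param kernels strip-convolution kernel sizes.
#' @param proj_init initializer for the two output projections; `"zeros"`
#'   makes the head (and hence the residual MDMSC block) start as the
#'   identity contribution.
#' @return a layer module.
#' @export
nn_mca_head <- function(channels, kernels = c(7L, 11L, 21L), proj_init = "uniform") {
  self <- new_module("nn_mca_head")
  scale <- 1 / sqrt(channels)
  self$children <- list(
    branch_x = nn_msc_branch(channels, "x", kernels),
    branch_y = nn_msc_branch(channels, "y", kernels),
    attn_x = nn_axattn("x", scale),
    attn_y = nn_axattn("y", scale),
    proj_t = nn_conv2d(channels, channels, kernel = c(1L, 1L), init = proj_init),
    proj_b = nn_conv2d(channels, channels, kernel = c(1L, 1L), init = proj_init))
  self$fw <- function(x, training = FALSE) {
    ch <- self$children
    fx <- ch$branch_x$fw(x, training)
    fy <- ch$branch_y$fw(x, training)
    ft <- ch$attn_x$fw(fy, fx, fx, training)
    fb <- ch$attn_y$fw(fx, fy, fy, training)
    ch$proj_t$fw(ft, training) + ch$proj_b$fw(fb, training)
  }
  self$bw <- function(dy) {
    ch <- self$children
    dft <- ch$proj_t$bw(dy)
    dfb <- ch$proj_b$bw(dy)
    gx <- ch$attn_x$bw(dft)   # q = fy, k = v = fx
    gy <- ch$attn_y$bw(dfb)   # q = fx, k = v = fy
    dfx <- gx$dk + gx$dv + gy$dq
    dfy <- gx$dq + gy$dk + gy$dv
    ch$branch_x$bw(dfx) + ch$branch_y$bw(dfy)
  }
  self
}

#' Multi-head multi-scale cross-axis attention block
#'
#' Splits the input channels into `num_heads` contiguous groups, applies an
#' independent [nn_mca_head()] to each, concatenates the head outputs in
#' order, and adds the block input (residual connection).
#'
#' @param channels input/output channel count.
#' @param num_heads number of heads; must divide `channels`.
#' @param kernels strip-convolution kernel sizes.
#' @param proj_init initializer for the heads' output projections.
#' @return a layer module whose forward pass preserves the input shape.
#' @export
nn_mdmsc <- function(channels, num_heads = 8L, kernels = c(7L, 11L, 21L),
                     proj_init = "uniform") {
  if (channels %% num_heads != 0L)
    stop("num_heads (", num_heads, ") must divide the channel count (",
         channels, ")")
  d <- channels %/% num_heads
  self <- new_module("nn_mdmsc")
  heads <- lapply(seq_len(num_heads), function(i) nn_mca_head(d, kernels, proj_init))
  names(heads) <- paste0("head", seq_len(num_heads))
  self$children <- heads
  self$meta <- list(channels = as.integer(channels),
                    num_heads = as.integer(num_heads), d = as.integer(d))
  self$fw <- function(x, training = FALSE) {
    if (dim(x)[3] != channels)
      stop("expected ", channels, " channels, got ", dim(x)[3])
    y <- x
    for (i in seq_len(num_heads)) {
      sl <- ((i - 1L) * d + 1L):(i * d)
      hs <- self$children[[i]]$fw(x[, , sl, , drop = FALSE], training)
      y[, , sl, ] <- x[, , sl, , drop = FALSE] + hs
    }
    y
  }
  self$bw <- function(dy) {
    dx <- dy
    for (i in seq_len(num_heads)) {
      sl <- ((i - 1L) * d + 1L):(i * d)
      dh <- self$children[[i]]$bw(dy[, , sl, , drop = FALSE])
      dx[, , sl, ] <- dy[, , sl, , drop = FALSE] + dh
    }
    dx
  }
  self
}

#' Apply an MDMSC block functionally
#'
#' Convenience wrapper building and applying [nn_mdmsc()]; mainly useful for
#' experimentation. For training, build the block once and reuse it.
#'
#' @param x feature map `(H, W, C)` or `(H, W, C, N)`.
#' @inheritParams nn_mdmsc
#' @return an array with the same shape as `x`.
#' @export
mdmsc <- function(x, num_heads = 8L, kernels = c(7L, 11L, 21L),
                  proj_init = "uniform") {
  x <- as_batch(x)
  block <- nn_mdmsc(dim(x)[3], num_heads, kernels, proj_init)
  y <- block$fw(x)
  if (isTRUE(attr(x, "squeeze"))) dim(y) <- dim(y)[1:3]
  y
}
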