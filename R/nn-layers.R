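# Leaf layers. Forward caches whatever the matching backward needs; backward
# accumulates parameter gradients into `grads` and returns the input gradient.

#' 2-D convolution layer ('same' padding, optional channel groups)
#'
#' @param in_ch,out_ch input / output channel counts.
#' @param kernel integer length-2 kernel size `c(kh, kw)`; both entries must be
#'   odd so that 'same' padding is symmetric.
#' @param groups channel groups; must divide both `in_ch` and `out_ch`.
#' @param bias include an additive bias per output channel.
#' @param init `"uniform"` for fan-in uniform initialization, `"zeros"` to
#'   zero-initialize (used e.g. to make residual blocks start as the identity).
#' @return a layer module with `fw(x, training)` and `bw(dy)` closures.
#' @export
nn_conv2d <- function(in_ch, out_ch, kernel = c(3L, 3L), groups = 1L,
                      bias = TRUE, init = "uniform") {
  kernel <- as.integer(rep(kernel, length.out = 2L))
  if (any(kernel %% 2L == 0L))
    stop("convolution kernel sizes must be odd for symmetric 'same' padding, got ",
         paste(kernel, collapse = "x"))
  if (in_ch %% groups != 0L || out_ch %% groups != 0L)
    stop("groups (", groups, ") must divide in_ch (", in_ch,
         ") and out_ch (", out_ch, ")")
  self <- new_module("nn_conv2d")
  cig <- in_ch %/% groups
  fan <- prod(kernel) * cig
  wd <- c(kernel, cig, out_ch)
  self$meta <- list(in_ch = in_ch, out_ch = out_ch, kernel = kernel,
                    groups = as.integer(groups), bias = bias)
  self$params$W <- if (init == "zeros") array(0, wd) else fan_in_uniform(wd, fan)
  if (bias) {
    self$params$b <- if (init == "zeros") numeric(out_ch) else
      as.numeric(fan_in_uniform(out_ch, fan))
  }
  self$grads <- lapply(self$params, function(p) array(0, dim_of(p)))
  self$fw <- function(x, training = FALSE) {
    if (dim(x)[3] != in_ch)
      stop("expected ", in_ch, " input channels, got ", dim(x)[3])
    self$cache_x <- x
    cpp_conv2d_fw(x, dim(x), self$params$W, dim(self$params$W),
                  if (bias) self$params$b else numeric(0), self$meta$groups)
  }
  self$bw <- function(dy) {
    r <- cpp_conv2d_bw(self$cache_x, dim(self$cache_x), self$params$W,
                       dim(self$params$W), dy, self$meta$groups, bias)
    self$grads$W <- self$grads$W + r$dw
    if (bias) self$grads$b <- self$grads$b + r$db
    r$dx
  }
  self
}

# Depthwise 1-D ("strip") convolution along one spatial axis: kernel 1 x k for
# the x axis, k x 1 for the y axis, one filter per channel.
nn_dwconv1d <- function(channels, k, axis = c("x", "y"), bias = TRUE) {
  axis <- match.arg(axis)
  kernel <- if (axis == "x") c(1L, as.integer(k)) else c(as.integer(k), 1L)
  nn_conv2d(channels, channels, kernel = kernel, groups = channels, bias = bias)
}

nn_maxpool2 <- function() {
  self <- new_module("nn_maxpool2")
  self$fw <- function(x, training = FALSE) {
    if (any(dim(x)[1:2] < 2L))
      stop("spatial size ", dim(x)[1], "x", dim(x)[2], " too small for 2x2 pooling")
    self$cache_dim <- dim(x)
    r <- cpp_maxpool2_fw(x, dim(x))
    self$cache_idx <- r$idx
    r$y
  }
  self$bw <- function(dy) cpp_maxpool2_bw(dy, self$cache_idx, self$cache_dim)
  self
}

# Parameter-free bilinear 2x upsampling (half-pixel centres, clamped edges).
nn_upsample2 <- function() {
  self <- new_module("nn_upsample2")
  self$fw <- function(x, training = FALSE) {
    self$cache_dim <- dim(x)
    cpp_upsample2_fw(x, dim(x))
  }
  self$bw <- function(dy) cpp_upsample2_bw(dy, self$cache_dim)
  self
}

nn_relu <- function() {
  self <- new_module("nn_relu")
  self$fw <- function(x, training = FALSE) {
    self$cache_mask <- x > 0
    x * self$cache_mask
  }
  self$bw <- function(dy) dy * self$cache_mask
  self
}

# Layer normalization over the channel vector at every spatial position,
# with learnable per-channel gain and bias.
nn_layernorm <- function(channels, eps = 1e-5) {
  if (channels < 1L) stop("layer normalization needs at least one channel")
  self <- new_module("nn_layernorm")
  self$meta <- list(channels = as.integer(channels), eps = eps)
  self$params$gain <- rep(1, channels)
  self$params$bias <- rep(0, channels)
  self$grads <- lapply(self$params, function(p) array(0, dim_of(p)))
  self$fw <- function(x, training = FALSE) {
    r <- cpp_layernorm_fw(x, dim(x), self$params$gain, self$params$bias, eps)
    self$cache <- list(xhat = r$xhat, invstd = r$invstd, d = dim(x))
    r$y
  }
  self$bw <- function(dy) {
    r <- cpp_layernorm_bw(dy, self$cache$xhat, self$cache$invstd,
                          self$params$gain, self$cache$d)
    self$grads$gain <- self$grads$gain + r$dgain
    self$grads$bias <- self$grads$bias + r$dbias
    r$dx
  }
  self
}

nn_batchnorm <- function(channels, momentum = 0.1, eps = 1e-5) {
  self <- new_module("nn_batchnorm")
  self$meta <- list(channels = as.integer(channels), momentum = momentum, eps = eps)
  self$params$gamma <- rep(1, channels)
  self$params$beta <- rep(0, channels)
  self$grads <- lapply(self$params, function(p) array(0, dim_of(p)))
  self$buffers$running_mean <- rep(0, channels)
  self$buffers$running_var <- rep(1, channels)
  self$fw <- function(x, training = FALSE) {
    r <- cpp_batchnorm_fw(x, dim(x), self$params$gamma, self$params$beta,
                          self$buffers$running_mean, self$buffers$running_var,
                          momentum, training, eps)
    if (training) {
      self$buffers$running_mean <- r$rmean
      self$buffers$running_var <- r$rvar
    }
    self$cache <- list(xhat = r$xhat, invstd = r$invstd, d = dim(x))
    r$y
  }
  self$bw <- function(dy) {
    r <- cpp_batchnorm_bw(dy, self$cache$xhat, self$cache$invstd,
                          self$params$gamma, self$cache$d)
    self$grads$gamma <- self$grads$gamma + r$dgamma
    self$grads$beta <- self$grads$beta + r$dbeta
    r$dx
  }
  self
}

# (Conv3x3 -> ReLU) x 2, the convolutional unit used throughout the encoder
# and decoder.
nn_double_conv <- function(in_ch, out_ch) {
  self <- new_module("nn_double_conv")
  self$children <- list(conv1 = nn_conv2d(in_ch, out_ch),
                        relu1 = nn_relu(),
                        conv2 = nn_conv2d(out_ch, out_ch),
                        relu2 = nn_relu())
  self$fw <- function(x, training = FALSE) {
    for (ch in self$children) x <- ch$fw(x, training)
    x
  }
  self$bw <- function(dy) {
    for (ch in rev(self$children)) dy <- ch$bw(dy)
    dy
  }
  self
}
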