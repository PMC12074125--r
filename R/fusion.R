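# Efficient feature fusion (EF) replacing plain skip-connection
# concatenation: a gated spatial attention (EA) computed from the upsampled
# decoder feature g and the encoder skip feature x, followed by channel
# attention with a residual (EC) on the concatenation of the gated skip and g.

#' Gated attention (EA) block
#'
#' `Wg = ReLU(BN(GroupConv(g)))`, `Wx = ReLU(BN(GroupConv(x)))`,
#' `gate = Sigmoid(Conv1x1(ReLU(Wg + Wx)))` — a single-channel spatial map in
#' (0,1) — and the output is `x * (1 + gate)`, the gate broadcast over
#' channels. The group convolutions are 3x3 with (up to) 32 groups and map
#' both inputs to `channels(x)` intermediate channels.
#'
#' @param g_ch,x_ch channel counts of the upsampled decoder map `g` and the
#'   skip map `x`.
#' @param groups requested group count for the two group convolutions
#'   (clamped to a common divisor of the channel counts involved).
#' @return a layer module with `fw(g, x, training)`.
#' @export
nn_ea <- function(g_ch, x_ch, groups = 32L) {
  self <- new_module("nn_ea")
  gg <- effective_groups(groups, g_ch, x_ch)
  gx <- effective_groups(groups, x_ch, x_ch)
  self$children <- list(
    conv_g = nn_conv2d(g_ch, x_ch, kernel = c(3L, 3L), groups = gg, bias = FALSE),
    bn_g = nn_batchnorm(x_ch),
    relu_g = nn_relu(),
    conv_x = nn_conv2d(x_ch, x_ch, kernel = c(3L, 3L), groups = gx, bias = FALSE),
    bn_x = nn_batchnorm(x_ch),
    relu_x = nn_relu(),
    relu_s = nn_relu(),
    psi = nn_conv2d(x_ch, 1L, kernel = c(1L, 1L)))
  self$meta <- list(g_ch = g_ch, x_ch = x_ch, groups = c(gg, gx))
  self$fw <- function(g, x, training = FALSE) {
    if (!identical(dim(g)[c(1, 2, 4)], dim(x)[c(1, 2, 4)]))
      stop("g and x must share spatial size and batch size (got ",
           paste(dim(g)[1:2], collapse = "x"), " vs ",
           paste(dim(x)[1:2], collapse = "x"), ")")
    ch <- self$children
    wg <- ch$relu_g$fw(ch$bn_g$fw(ch$conv_g$fw(g, training), training), training)
    wx <- ch$relu_x$fw(ch$bn_x$fw(ch$conv_x$fw(x, training), training), training)
    s <- ch$relu_s$fw(wg + wx, training)
    z <- ch$psi$fw(s, training)
    gate <- sigmoid(z)                       # (H, W, 1, N)
    self$cache <- list(x = x, gate = gate)
    gb <- gate[, , rep(1L, dim(x)[3]), , drop = FALSE]
    x * (1 + gb)
  }
  self$bw <- function(dy) {
    ch <- self$children
    x <- self$cache$x; gate <- self$cache$gate
    gb <- gate[, , rep(1L, dim(x)[3]), , drop = FALSE]
    dx_direct <- dy * (1 + gb)
    # d/dgate of sum(dy * x * (1+gate)) summed over channels
    dgate <- apply(dy * x, c(1, 2, 4), sum)
    dim(dgate) <- dim(gate)
    dz <- dgate * gate * (1 - gate)
    ds <- ch$psi$bw(dz)
    dsum <- ch$relu_s$bw(ds)
    dx_gatepath <- ch$conv_x$bw(ch$bn_x$bw(ch$relu_x$bw(dsum)))
    dg <- ch$conv_g$bw(ch$bn_g$bw(ch$relu_g$bw(dsum)))
    list(dg = dg, dx = dx_direct + dx_gatepath)
  }
  self
}

#' Channel attention with residual (EC) block
#'
#' Global average pooling gives one descriptor per channel; a 1x1 convolution
#' (full C-to-C by default, or an ECA-style 1-D convolution across channels
#' with `style = "eca"`) and a sigmoid give per-channel weights in (0,1); the
#' output is `u * w + u` with the weights broadcast spatially.
#'
#' @param channels channel count.
#' @param style `"conv"` for the full `C x C` 1x1 convolution, `"eca"` for a
#'   parameter-light 1-D convolution (kernel `eca_k`) across the channel
#'   descriptor.
#' @param eca_k kernel size of the ECA-style variant.
#' @return a layer module.
#' @export
nn_ec <- function(channels, style = c("conv", "eca"), eca_k = 3L) {
  style <- match.arg(style)
  self <- new_module("nn_ec")
  if (style == "conv") {
    self$children <- list(proj = nn_conv2d(channels, channels, kernel = c(1L, 1L)))
  } else {
    self$params$w <- as.numeric(fan_in_uniform(eca_k, eca_k))
    self$grads$w <- numeric(eca_k)
  }
  self$meta <- list(channels = as.integer(channels), style = style,
                    eca_k = as.integer(eca_k))
  eca_apply <- function(s) {
    # 'same'-padded 1-D conv of the length-C descriptor, per sample
    k <- self$meta$eca_k; p <- (k - 1L) %/% 2L
    C <- dim(s)[3]; N <- dim(s)[4]
    out <- s
    for (n in seq_len(N)) {
      v <- s[1, 1, , n]
      padded <- c(numeric(p), v, numeric(p))
      out[1, 1, , n] <- vapply(seq_len(C), function(c)
        sum(self$params$w * padded[c:(c + k - 1L)]), numeric(1))
    }
    out
  }
  self$fw <- function(u, training = FALSE) {
    HW <- prod(dim(u)[1:2])
    s <- apply(u, c(3, 4), mean)                      # C x N
    sd4 <- array(s, c(1, 1, dim(u)[3], dim(u)[4]))
    z <- if (style == "conv") self$children$proj$fw(sd4, training) else eca_apply(sd4)
    w <- sigmoid(z)                                   # (1,1,C,N)
    self$cache <- list(u = u, w = w, s = sd4, HW = HW)
    wb <- aperm(array(w[1, 1, , ], dim(u)[c(3, 4, 1, 2)]), c(3, 4, 1, 2))
    u * wb + u
  }
  self$bw <- function(dy) {
    u <- self$cache$u; w <- self$cache$w; HW <- self$cache$HW
    wb <- aperm(array(w[1, 1, , ], dim(u)[c(3, 4, 1, 2)]), c(3, 4, 1, 2))
    du <- dy * (1 + wb)
    dw <- apply(dy * u, c(3, 4), sum)                 # C x N
    dz <- array(dw, dim(w)) * w * (1 - w)
    if (style == "conv") {
      ds <- self$children$proj$bw(dz)
    } else {
      k <- self$meta$eca_k; p <- (k - 1L) %/% 2L
      C <- dim(u)[3]; N <- dim(u)[4]
      ds <- array(0, dim(dz))
      for (n in seq_len(N)) {
        v <- self$cache$s[1, 1, , n]
        padded <- c(numeric(p), v, numeric(p))
        dpad <- numeric(C + 2L * p)
        for (c in seq_len(C)) {
          self$grads$w <- self$grads$w + dz[1, 1, c, n] * padded[c:(c + k - 1L)]
          dpad[c:(c + k - 1L)] <- dpad[c:(c + k - 1L)] + dz[1, 1, c, n] * self$params$w
        }
        ds[1, 1, , n] <- dpad[(p + 1L):(p + C)]
      }
    }
    # ds is d/d(pooled descriptor); spread uniformly over positions
    dsb <- aperm(array(ds[1, 1, , ], dim(u)[c(3, 4, 1, 2)]), c(3, 4, 1, 2))
    du + dsb / HW
  }
  self
}

#' Efficient feature fusion (EF) block
#'
#' `EC( concat_channels( EA(g, x), g ) )`; output channel count is
#' `channels(x) + channels(g)`.
#'
#' @inheritParams nn_ea
#' @param ec_style passed to [nn_ec()].
#' @return a layer module with `fw(g, x, training)`.
#' @export
nn_ef <- function(g_ch, x_ch, groups = 32L, ec_style = "conv") {
  self <- new_module("nn_ef")
  self$children <- list(ea = nn_ea(g_ch, x_ch, groups),
                        ec = nn_ec(x_ch + g_ch, ec_style))
  self$meta <- list(g_ch = g_ch, x_ch = x_ch)
  self$fw <- function(g, x, training = FALSE) {
    a <- self$children$ea$fw(g, x, training)
    u <- abind4(a, g)
    self$children$ec$fw(u, training)
  }
  self$bw <- function(dy) {
    du <- self$children$ec$bw(dy)
    x_ch <- self$meta$x_ch
    da <- du[, , seq_len(x_ch), , drop = FALSE]
    dg2 <- du[, , x_ch + seq_len(self$meta$g_ch), , drop = FALSE]
    r <- self$children$ea$bw(da)
    list(dg = r$dg + dg2, dx = r$dx)
  }
  self
}

# Channel concatenation of two (H,W,C,N) arrays.
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[c(1, 2, 4)], db[c(1, 2, 4)]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Apply a gated-attention (EA) fusion functionally
#'
#' Builds a fresh [nn_ea()] block (random weights) and applies it; mainly for
#' demonstration and testing of the gating contract.
#'
#' @param g,x feature maps `(H, W, C[, N])` with identical spatial size.
#' @inheritParams nn_ea
#' @return gated map shaped like `x`.
#' @export
ea_gate <- function(g, x, groups = 32L) {
  g <- as_batch(g); x <- as_batch(x)
  block <- nn_ea(dim(g)[3], dim(x)[3], groups)
  y <- block$fw(g, x, training = TRUE)
  if (isTRUE(attr(x, "squeeze"))) dim(y) <- dim(y)[1:3]
  y
}

#' Apply channel attention (EC) functionally
#'
#' @param u feature map `(H, W, C[, N])`.
#' @inheritParams nn_ec
#' @return array shaped like `u`.
#' @export
ec_attention <- function(u, style = "conv", eca_k = 3L) {
  u <- as_batch(u)
  block <- nn_ec(dim(u)[3], style, eca_k)
  y <- block$fw(u, training = TRUE)
  if (isTRUE(attr(u, "squeeze"))) dim(y) <- dim(y)[1:3]
  y
}

#' Apply efficient feature fusion functionally
#'
#' @inheritParams ea_gate
#' @param ec_style passed to [nn_ec()].
#' @return fused map with `channels(x) + channels(g)` channels.
#' @export
ef_fuse <- function(g, x, groups = 32L, ec_style = "conv") {
  g <- as_batch(g); x <- as_batch(x)
  block <- nn_ef(dim(g)[3], dim(x)[3], groups, ec_style)
  y <- block$fw(g, x, training = TRUE)
  if (isTRUE(attr(x, "squeeze"))) dim(y) <- dim(y)[1:3]
  y
}
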