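# U-shaped encoder-decoder assembly.
#
# The encoder is `depth` convolutional modules (two 3x3 convs + ReLU, then
# 2x2 max pooling) with widths base_width * 2^(k-1). A multi-head multi-scale
# cross-axis attention block is applied to every pooled map. The deepest
# pooled (and attended) map feeds the decoder directly; upsampling is
# parameter-free bilinear, so channel counts are carried unchanged into each
# fusion. Each decoder module fuses the upsampled map with the same-resolution
# encoder skip (gated EF fusion, or plain concatenation when ablated) and
# applies two 3x3 convs down to the skip's width. A 1x1 convolution and
# sigmoid produce the per-pixel foreground probability.

#' Network configuration
#'
#' @param in_channels input image channels (3 for RGB).
#' @param base_width channel count of the first encoder stage; stage k uses
#'   `base_width * 2^(k-1)`.
#' @param depth number of encoder (= decoder) modules.
#' @param num_heads attention heads per MDMSC block; must divide `base_width`.
#' @param use_mdmsc apply cross-axis attention to each pooled map.
#' @param use_ef use gated efficient feature fusion instead of plain
#'   concatenation at the skip connections.
#' @param out_channels output channels (1 for binary segmentation).
#' @param groups requested group count of the EA group convolutions.
#' @param ec_style `"conv"` or `"eca"`, see [nn_ec()].
#' @return a `network_config` list.
#' @export
network_config <- function(in_channels = 3L, base_width = 64L, depth = 4L,
                           num_heads = 8L, use_mdmsc = TRUE, use_ef = TRUE,
                           out_channels = 1L, groups = 32L, ec_style = "conv") {
  cfg <- list(in_channels = as.integer(in_channels),
              base_width = as.integer(base_width),
              depth = as.integer(depth),
              num_heads = as.integer(num_heads),
              use_mdmsc = isTRUE(use_mdmsc),
              use_ef = isTRUE(use_ef),
              out_channels = as.integer(out_channels),
              groups = as.integer(groups),
              ec_style = ec_style)
  if (cfg$depth < 1L) stop("depth must be at least 1")
  if (cfg$base_width < 1L || cfg$in_channels < 1L || cfg$out_channels < 1L)
    stop("channel counts must be positive")
  if (cfg$base_width %% cfg$num_heads != 0L)
    stop("num_heads (", cfg$num_heads, ") must divide base_width (",
         cfg$base_width, ")")
  class(cfg) <- "network_config"
  cfg
}

#' Encoder module: double conv then 2x2 max pooling
#'
#' @param in_ch,out_ch channel counts.
#' @return a layer module; `fw(x)` returns `list(skip, pooled)` where `skip`
#'   keeps the input resolution and `pooled` halves it.
#' @export
nn_encoder_block <- function(in_ch, out_ch) {
  self <- new_module("nn_encoder_block")
  self$children <- list(conv = nn_double_conv(in_ch, out_ch),
                        pool = nn_maxpool2())
  self$fw <- function(x, training = FALSE) {
    skip <- self$children$conv$fw(x, training)
    list(skip = skip, pooled = self$children$pool$fw(skip, training))
  }
  # dskip_extra: gradient reaching the skip output from the decoder side
  self$bw <- function(dpooled, dskip_extra = 0) {
    self$children$conv$bw(self$children$pool$bw(dpooled) + dskip_extra)
  }
  self
}

#' Decoder module: upsample, fuse with skip, double conv
#'
#' @param g_ch channels of the incoming (deeper) map.
#' @param x_ch channels of the encoder skip at the target resolution.
#' @param out_ch output width (the skip width in the default schedule).
#' @param use_ef gated EF fusion (`TRUE`) or plain concatenation.
#' @param groups,ec_style fusion options, see [nn_ef()].
#' @return a layer module with `fw(g, skip, training)`.
#' @export
nn_decoder_block <- function(g_ch, x_ch, out_ch, use_ef = TRUE, groups = 32L,
                             ec_style = "conv") {
  self <- new_module("nn_decoder_block")
  self$children <- list(up = nn_upsample2())
  if (use_ef) self$children$fuse <- nn_ef(g_ch, x_ch, groups, ec_style)
  self$children$conv <- nn_double_conv(x_ch + g_ch, out_ch)
  self$meta <- list(g_ch = g_ch, x_ch = x_ch, use_ef = use_ef)
  self$fw <- function(g, skip, training = FALSE) {
    gu <- self$children$up$fw(g, training)
    if (!identical(dim(gu)[1:2], dim(skip)[1:2]))
      stop("upsampled map (", paste(dim(gu)[1:2], collapse = "x"),
           ") does not match skip resolution (",
           paste(dim(skip)[1:2], collapse = "x"), ")")
    u <- if (self$meta$use_ef) self$children$fuse$fw(gu, skip, training)
         else abind4(skip, gu)
    self$children$conv$fw(u, training)
  }
  self$bw <- function(dy) {
    du <- self$children$conv$bw(dy)
    if (self$meta$use_ef) {
      r <- self$children$fuse$bw(du)
      dgu <- r$dg; dskip <- r$dx
    } else {
      x_ch <- self$meta$x_ch
      dskip <- du[, , seq_len(x_ch), , drop = FALSE]
      dgu <- du[, , x_ch + seq_len(self$meta$g_ch), , drop = FALSE]
    }
    list(dg = self$children$up$bw(dgu), dskip = dskip)
  }
  self
}

#' Build the segmentation model
#'
#' @param config a [network_config()].
#' @return a model module with `fw(x, training)` returning logits,
#'   `bw(dlogits)`, and the configuration in `$config`.
#' @export
build_model <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  depth <- config$depth
  widths <- config$base_width * 2L^(seq_len(depth) - 1L)
  self <- new_module("axu_model")
  self$config <- config
  ch <- list()
  ins <- c(config$in_channels, widths[-depth])
  for (k in seq_len(depth)) {
    ch[[paste0("enc", k)]] <- nn_encoder_block(ins[k], widths[k])
    if (config$use_mdmsc)
      ch[[paste0("att", k)]] <- nn_mdmsc(widths[k], config$num_heads)
  }
  # decoder runs deepest-first: g carries widths[depth], widths[depth], ...,
  # fused with skips widths[depth], widths[depth-1], ..., widths[1]
  g_ch <- widths[depth]
  for (k in seq_len(depth)) {
    x_ch <- widths[depth - k + 1L]
    ch[[paste0("dec", k)]] <- nn_decoder_block(
      g_ch, x_ch, out_ch = x_ch, use_ef = config$use_ef,
      groups = config$groups, ec_style = config$ec_style)
    g_ch <- x_ch
  }
  ch$head <- nn_conv2d(widths[1], config$out_channels, kernel = c(1L, 1L))
  self$children <- ch
  self$fw <- function(x, training = FALSE) {
    d <- dim(x)
    if (d[1] %% 2L^depth != 0L || d[2] %% 2L^depth != 0L)
      stop("input height and width must be divisible by ", 2L^depth,
           " (got ", d[1], "x", d[2], ")")
    if (d[3] != config$in_channels)
      stop("expected ", config$in_channels, " input channels, got ", d[3])
    skips <- vector("list", depth)
    h <- x
    for (k in seq_len(depth)) {
      r <- self$children[[paste0("enc", k)]]$fw(h, training)
      skips[[k]] <- r$skip
      h <- r$pooled
      if (config$use_mdmsc) h <- self$children[[paste0("att", k)]]$fw(h, training)
    }
    for (k in seq_len(depth)) {
      h <- self$children[[paste0("dec", k)]]$fw(h, skips[[depth - k + 1L]], training)
    }
    self$children$head$fw(h, training)
  }
  self$bw <- function(dlogits) {
    dh <- self$children$head$bw(dlogits)
    dskips <- vector("list", depth)
    for (k in rev(seq_len(depth))) {
      r <- self$children[[paste0("dec", k)]]$bw(dh)
      dh <- r$dg
      dskips[[depth - k + 1L]] <- r$dskip
    }
    for (k in rev(seq_len(depth))) {
      if (config$use_mdmsc) dh <- self$children[[paste0("att", k)]]$bw(dh)
      dh <- self$children[[paste0("enc", k)]]$bw(dh, dskips[[k]])
    }
    dh
  }
  self
}

#' Forward pass to foreground probabilities
#'
#' @param model a model from [build_model()].
#' @param x image batch `(H, W, C)` or `(H, W, C, N)` with values in `[0, 1]`.
#' @param training propagate in training mode (batch-norm batch statistics).
#' @return per-pixel probabilities in (0, 1), same spatial shape as the input.
#' @export
model_predict <- function(model, x, training = FALSE) {
  x <- as_batch(x)
  p <- sigmoid(model$fw(x, training))
  if (isTRUE(attr(x, "squeeze"))) dim(p) <- dim(p)[1:3]
  p
}

#' Count trainable parameters
#'
#' @param model a model (or any layer module).
#' @return a `model_summary` list with `total` and a data frame `breakdown`
#'   of per-submodule counts summing to the total.
#' @export
count_parameters <- function(model) {
  entries <- collect_parameters(model)
  if (!length(entries)) {
    out <- list(total = 0,
                breakdown = data.frame(name = character(0), count = numeric(0)))
    class(out) <- "model_summary"
    return(out)
  }
  counts <- vapply(entries, function(e) length(e$env$params[[e$name]]), numeric(1))
  top <- vapply(entries, function(e) sub("\\..*$", "", e$path), character(1))
  agg <- tapply(counts, top, sum)
  out <- list(total = sum(counts),
              breakdown = data.frame(name = names(agg),
                                     count = as.numeric(agg),
                                     row.names = NULL))
  class(out) <- "model_summary"
  out
}

#' @export
print.model_summary <- function(x, ...) {
  cat("Trainable parameters:", format(x$total, big.mark = ","),
      sprintf("(%.2f M)\n", x$total / 1e6))
  for (i in seq_len(nrow(x$breakdown)))
    cat(sprintf("  %-8s %12s\n", x$breakdown$name[i],
                format(x$breakdown$count[i], big.mark = ",")))
  invisible(x)
}
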