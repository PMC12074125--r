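# Independent oracles used across the suite. These deliberately use naive
# loops so they share no code with the implementation they check.

# Naive triple-loop axial attention on a single (H,W,C) map.
oracle_axattn <- function(q, k, v, axis, scale) {
  H <- dim(q)[1]; W <- dim(q)[2]; C <- dim(q)[3]
  y <- array(0, dim(q))
  if (axis == "x") {
    for (h in seq_len(H)) {
      for (i in seq_len(W)) {
        logits <- numeric(W)
        for (j in seq_len(W)) logits[j] <- scale * sum(q[h, i, ] * k[h, j, ])
        wgt <- exp(logits - max(logits)); wgt <- wgt / sum(wgt)
        acc <- numeric(C)
        for (j in seq_len(W)) acc <- acc + wgt[j] * v[h, j, ]
        y[h, i, ] <- acc
      }
    }
  } else {
    for (w in seq_len(W)) {
      for (i in seq_len(H)) {
        logits <- numeric(H)
        for (j in seq_len(H)) logits[j] <- scale * sum(q[i, w, ] * k[j, w, ])
        wgt <- exp(logits - max(logits)); wgt <- wgt / sum(wgt)
        acc <- numeric(C)
        for (j in seq_len(H)) acc <- acc + wgt[j] * v[j, w, ]
        y[i, w, ] <- acc
      }
    }
  }
  y
}

# Brute-force pixel-loop confusion counts and metrics.
oracle_confusion <- function(pred, truth, threshold = 0.5) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    pos <- pred[i] >= threshold
    if (pos && truth[i] == 1) tp <- tp + 1
    else if (pos && truth[i] == 0) fp <- fp + 1
    else if (!pos && truth[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn,
       acc = (tp + tn) / (tp + fp + fn + tn),
       miou = ((if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)) +
                 (if (tn + fn + fp == 0) 1 else tn / (tn + fn + fp))) / 2,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

# 8-connected component count via flood fill.
oracle_n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  ncomp <- 0L
  for (sy in seq_len(nrow(mask))) for (sx in seq_len(ncol(mask))) {
    if (mask[sy, sx] && lab[sy, sx] == 0L) {
      ncomp <- ncomp + 1L
      queue <- list(c(sy, sx)); lab[sy, sx] <- ncomp
      while (length(queue)) {
        p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
        for (dy in -1:1) for (dx in -1:1) {
          y <- p[1] + dy; x <- p[2] + dx
          if (y >= 1 && y <= nrow(mask) && x >= 1 && x <= ncol(mask) &&
              mask[y, x] && lab[y, x] == 0L) {
            lab[y, x] <- ncomp
            queue[[length(queue) + 1L]] <- c(y, x)
          }
        }
      }
    }
  }
  ncomp
}

# Direct 1-D 'same'-padded convolution of a vector.
oracle_conv1d <- function(v, kern) {
  k <- length(kern); p <- (k - 1) / 2
  padded <- c(numeric(p), v, numeric(p))
  vapply(seq_along(v), function(i) sum(kern * padded[i:(i + k - 1)]), numeric(1))
}

# Set every bias-like parameter (b, bias, beta) of a module tree to zero.
zero_biases <- function(module) {
  for (e in axunet:::collect_parameters(module)) {
    if (e$name %in% c("b", "bias", "beta"))
      e$env$params[[e$name]][] <- 0
  }
  invisible(module)
}

rand_map <- function(h, w, c, n = 1L) array(rnorm(h * w * c * n), c(h, w, c, n))
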