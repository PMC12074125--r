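# Training / evaluation / prediction driver.
#
# Optimizer: Adam with beta1 configurable (the "momentum" of the published
# setup), beta2 = 0.999, L2 weight decay added to the gradient. The loss is
# binary cross-entropy computed on logits (numerically stable), optionally
# plus a soft-Dice term. All randomness (init, shuffling, augmentation)
# derives from the training seed.

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param beta1 first-moment decay (the published "momentum of 0.9").
#' @param beta2 second-moment decay.
#' @param weight_decay L2 coefficient added to gradients.
#' @param batch_size samples per step.
#' @param epochs passes over the training set.
#' @param seed master seed for init/shuffling/augmentation.
#' @param loss `"bce"` or `"bce_dice"`.
#' @param threshold binarization threshold for metrics.
#' @param augment_config optional [augmentation_config()] applied per sample
#'   per epoch; `NULL` disables augmentation.
#' @return a `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                            weight_decay = 1e-8, batch_size = 4L, epochs = 1L,
                            seed = 1L, loss = c("bce", "bce_dice"),
                            threshold = 0.5, augment_config = NULL) {
  loss <- match.arg(loss)
  if (learning_rate < 0) stop("learning_rate must be nonnegative")
  if (beta1 < 0 || beta1 >= 1) stop("beta1 must be in [0, 1)")
  if (epochs < 1L) stop("epochs must be at least 1")
  if (batch_size < 1L) stop("batch_size must be at least 1")
  cfg <- list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
              weight_decay = weight_decay, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), seed = as.integer(seed),
              loss = loss, threshold = threshold,
              augment_config = augment_config)
  class(cfg) <- "training_config"
  cfg
}

# Stack samples into (H,W,C,N) image and (H,W,1,N) mask batches.
stack_batch <- function(samples) {
  d <- dim(samples[[1]]$image)
  n <- length(samples)
  x <- array(0, c(d[1], d[2], d[3], n))
  y <- array(0, c(d[1], d[2], 1, n))
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]$image
    y[, , 1, i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

# BCE (+ optional soft Dice) on logits; returns loss and dloss/dlogits.
seg_loss <- function(z, y, kind = "bce") {
  n <- length(z)
  p <- sigmoid(z)
  bce <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  dz <- (p - y) / n
  loss <- bce
  if (kind == "bce_dice") {
    sp <- sum(p); sy <- sum(y); spy <- sum(p * y)
    dice <- 1 - (2 * spy + 1) / (sp + sy + 1)
    # d dice / dp, then chain through sigmoid
    ddice_dp <- -(2 * y * (sp + sy + 1) - (2 * spy + 1)) / (sp + sy + 1)^2
    dz <- dz + ddice_dp * p * (1 - p)
    loss <- loss + dice
  }
  list(loss = loss, dz = dz)
}

new_adam <- function(entries, lr, beta1, beta2, weight_decay, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(entries, function(e) array(0, dim_of(e$env$params[[e$name]])))
  st$v <- lapply(entries, function(e) array(0, dim_of(e$env$params[[e$name]])))
  st$t <- 0L
  step <- function() {
    st$t <- st$t + 1L
    bc1 <- 1 - beta1^st$t
    bc2 <- 1 - beta2^st$t
    for (i in seq_along(entries)) {
      e <- entries[[i]]
      g <- e$env$grads[[e$name]]
      if (weight_decay > 0) g <- g + weight_decay * e$env$params[[e$name]]
      st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
      st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
      p <- e$env$params[[e$name]]
      upd <- p - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
      attributes(upd) <- attributes(p)
      e$env$params[[e$name]] <- upd
    }
  }
  list(step = step, state = st)
}

#' Train a model
#'
#' @param model a model from [build_model()].
#' @param train_set list of `segmentation_sample`s.
#' @param config a [training_config()].
#' @param val_set optional validation set; per-epoch pooled metrics are
#'   appended to the log.
#' @param verbose print one line per epoch.
#' @return the trained model (modified in place), with the epoch log in
#'   `attr(, "log")`: a data frame with columns epoch, mean_loss and, with a
#'   validation set, miou/acc/recall. The per-epoch batch orders are stored in
#'   `attr(log, "batch_order")`.
#' @export
train_model <- function(model, train_set, config = training_config(),
                        val_set = NULL, verbose = FALSE) {
  if (!length(train_set)) stop("training set is empty")
  set.seed(config$seed)
  entries <- collect_parameters(model)
  opt <- new_adam(entries, config$learning_rate, config$beta1, config$beta2,
                  config$weight_decay)
  n <- length(train_set)
  logs <- vector("list", config$epochs)
  batch_orders <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batch_orders[[ep]] <- ord
    losses <- c()
    for (b0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      batch_samples <- train_set[idx]
      if (!is.null(config$augment_config)) {
        batch_samples <- lapply(seq_along(batch_samples), function(j)
          augment(batch_samples[[j]], config$augment_config,
                  seed = (config$seed * 7919L + ep * 131L + idx[j]) %%
                    .Machine$integer.max))
      }
      bt <- stack_batch(batch_samples)
      z <- model$fw(bt$x, training = TRUE)
      l <- seg_loss(z, bt$y, config$loss)
      if (!is.finite(l$loss))
        stop("non-finite loss in epoch ", ep, ", batch starting at ", b0)
      zero_grads(model)
      model$bw(l$dz)
      opt$step()
      losses <- c(losses, l$loss)
    }
    row <- data.frame(epoch = ep, mean_loss = mean(losses))
    if (!is.null(val_set)) {
      m <- evaluate_model(model, val_set, threshold = config$threshold)
      row$miou <- m$pooled$miou; row$acc <- m$pooled$acc
      row$recall <- m$pooled$recall
    }
    logs[[ep]] <- row
    if (verbose)
      cat(sprintf("epoch %3d  mean_loss %.5f%s\n", ep, row$mean_loss,
                  if (!is.null(val_set)) sprintf("  miou %.4f", row$miou) else ""))
  }
  log <- do.call(rbind, logs)
  attr(log, "batch_order") <- batch_orders
  attr(model, "log") <- log
  model
}

#' Evaluate a model on a dataset
#'
#' @param model a model module, or a function `f(image_batch)` returning
#'   probability maps (useful for oracle predictors in tests).
#' @param test_set list of `segmentation_sample`s.
#' @param threshold binarization threshold.
#' @return list with `pooled` metrics (confusions summed over all images
#'   before computing miou/acc/recall), `per_image` means, and the pooled
#'   `confusion`.
#' @export
evaluate_model <- function(model, test_set, threshold = 0.5) {
  if (!length(test_set)) stop("test set is empty")
  fwd <- if (is.function(model)) model else function(x) model_predict(model, x)
  cms <- lapply(test_set, function(s) {
    x <- array(s$image, c(dim(s$image), 1L))
    p <- fwd(x)
    confusion(array(p, dim(s$mask)), s$mask, threshold)
  })
  pooled_cm <- cm_sum(cms)
  per <- vapply(cms, function(cm)
    c(miou = miou(cm), acc = accuracy(cm),
      recall = if (cm$TP + cm$FN > 0) recall(cm) else NA_real_), numeric(3))
  list(pooled = list(miou = miou(pooled_cm), acc = accuracy(pooled_cm),
                     recall = recall(pooled_cm)),
       per_image = list(miou = mean(per["miou", ]), acc = mean(per["acc", ]),
                        recall = mean(per["recall", ], na.rm = TRUE)),
       confusion = pooled_cm)
}

#' Segment an image file
#'
#' Reads a PNG, zero-pads it to the next multiple of `2^depth`, runs the
#' model, crops back, and writes the binary mask (and optionally a red
#' overlay) as PNG.
#'
#' @param model a trained model.
#' @param input_path input image (PNG; grayscale images are replicated to
#'   RGB).
#' @param output_path output mask PNG ({0, 255}).
#' @param overlay_path optional overlay PNG with the mask in red.
#' @param threshold binarization threshold.
#' @return the predicted binary mask matrix, invisibly.
#' @export
predict_image <- function(model, input_path, output_path,
                          overlay_path = NULL, threshold = 0.5) {
  if (!file.exists(input_path)) stop("cannot read input image: ", input_path)
  img <- png::readPNG(input_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  h <- dim(img)[1]; w <- dim(img)[2]
  f <- 2L^model$config$depth
  hp <- as.integer(ceiling(h / f) * f); wp <- as.integer(ceiling(w / f) * f)
  xp <- array(0, c(hp, wp, 3, 1))
  xp[1:h, 1:w, , 1] <- img
  p <- model_predict(model, xp)
  mask <- (p[1:h, 1:w, 1, 1] >= threshold) * 1
  png::writePNG(mask, output_path)
  if (!is.null(overlay_path)) {
    ov <- img
    r <- ov[, , 1]; r[mask == 1] <- 1
    g <- ov[, , 2]; g[mask == 1] <- g[mask == 1] * 0.3
    b <- ov[, , 3]; b[mask == 1] <- b[mask == 1] * 0.3
    ov[, , 1] <- r; ov[, , 2] <- g; ov[, , 3] <- b
    png::writePNG(ov, overlay_path)
  }
  invisible(mask)
}

#' Save / load model checkpoints
#'
#' The checkpoint stores the network configuration and all weights and
#' buffers; loading rebuilds the model and restores them bit-for-bit.
#'
#' @param model a model.
#' @param path checkpoint file.
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), state = state_dict(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(network_config, ck$config)
  model <- build_model(cfg)
  load_state_dict(model, ck$state)
  model
}

#' Run the four-variant ablation
#'
#' Trains and evaluates the {with/without attention} x {with/without EF
#' fusion} variants under identical seeds and data order, mirroring the
#' published ablation-table layout.
#'
#' @param net_config base [network_config()] (its `use_mdmsc`/`use_ef` flags
#'   are overridden per variant).
#' @param train_set,test_set sample lists.
#' @param train_config a [training_config()].
#' @param variants data frame with logical columns `mdmsc`, `ef`; default all
#'   four combinations.
#' @return a data frame with columns MDMSC, EF (as check marks), params,
#'   miou, acc, recall (percentages); per-variant batch-order hashes are in
#'   `attr(, "batch_order")`.
#' @export
run_ablation <- function(net_config, train_set, test_set,
                         train_config = training_config(),
                         variants = NULL) {
  if (is.null(variants))
    variants <- expand.grid(mdmsc = c(TRUE, FALSE), ef = c(TRUE, FALSE))
  rows <- vector("list", nrow(variants))
  orders <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    cfg <- net_config
    cfg$use_mdmsc <- variants$mdmsc[i]
    cfg$use_ef <- variants$ef[i]
    set.seed(train_config$seed)  # identical init stream per variant
    model <- build_model(cfg)
    model <- train_model(model, train_set, train_config)
    m <- evaluate_model(model, test_set, threshold = train_config$threshold)
    orders[[i]] <- attr(attr(model, "log"), "batch_order")
    rows[[i]] <- data.frame(
      MDMSC = ifelse(variants$mdmsc[i], "√", "×"),
      EF = ifelse(variants$ef[i], "√", "×"),
      params = count_parameters(model)$total,
      miou = round(100 * m$pooled$miou, 2),
      acc = round(100 * m$pooled$acc, 2),
      recall = round(100 * m$pooled$recall, 2))
  }
  out <- do.call(rbind, rows)
  attr(out, "batch_order") <- orders
  out
}
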