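# Geometric + photometric augmentation: rotation, translation, scaling (one
# affine transform applied identically to image and mask; bilinear for the
# image, nearest-neighbour for the mask so it stays strictly binary) and
# colour jitter (brightness / contrast / saturation, image only).

#' Augmentation configuration
#'
#' @param rotation_degrees interval of rotation angles.
#' @param translation_fraction interval of translations as a fraction of the
#'   image size (applied independently per axis).
#' @param scale_factor interval of isotropic scale factors (> 0).
#' @param brightness,contrast,saturation nonnegative jitter amplitudes; a
#'   factor is drawn from `[1 - a, 1 + a]` for each.
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(rotation_degrees = c(-30, 30),
                                translation_fraction = c(-0.1, 0.1),
                                scale_factor = c(0.9, 1.1),
                                brightness = 0.1, contrast = 0.1,
                                saturation = 0.1) {
  cfg <- list(rotation_degrees = as.numeric(rotation_degrees),
              translation_fraction = as.numeric(translation_fraction),
              scale_factor = as.numeric(scale_factor),
              brightness = brightness, contrast = contrast,
              saturation = saturation)
  if (any(cfg$scale_factor <= 0)) stop("scale factors must be positive")
  if (any(vapply(cfg[1:3], function(iv) diff(iv) < 0, logical(1))))
    stop("augmentation intervals must be nondecreasing")
  if (any(unlist(cfg[4:6]) < 0)) stop("jitter amplitudes must be nonnegative")
  class(cfg) <- "augmentation_config"
  cfg
}

# Inverse-map an output grid through rotation/scale/translation about the
# image centre; returns source coordinates (1-based, fractional).
affine_source_coords <- function(h, w, angle_deg, ty, tx, scale) {
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy - ty
  xx <- matrix(rep(seq_len(w), each = h), h, w) - cx - tx
  # inverse of (rotate by th, scale by s): rotate by -th, scale by 1/s
  sy <- (cos(th) * yy - sin(th) * xx) / scale + cy
  sx <- (sin(th) * yy + cos(th) * xx) / scale + cx
  list(sy = sy, sx = sx)
}

sample_plane_bilinear <- function(m, sy, sx) {
  h <- nrow(m); w <- ncol(m)
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  cl <- function(v, n) pmin(pmax(v, 1), n)
  inb <- sy >= 0.5 & sy <= h + 0.5 & sx >= 0.5 & sx <= w + 0.5
  g <- function(yy, xx) m[cbind(as.vector(cl(yy, h)), as.vector(cl(xx, w)))]
  v <- (1 - fy) * (1 - fx) * g(y0, x0) + fy * (1 - fx) * g(y0 + 1, x0) +
    (1 - fy) * fx * g(y0, x0 + 1) + fy * fx * g(y0 + 1, x0 + 1)
  out <- matrix(v, h, w)
  out[!inb] <- 0
  out
}

sample_plane_nearest <- function(m, sy, sx) {
  h <- nrow(m); w <- ncol(m)
  yr <- round(sy); xr <- round(sx)
  inb <- yr >= 1 & yr <= h & xr >= 1 & xr <= w
  out <- matrix(0, h, w)
  out[inb] <- m[cbind(yr[inb], xr[inb])]
  out
}

#' Augment a sample
#'
#' Draws one parameter per transform from the config's intervals (seeded),
#' applies the same geometric transform to image (bilinear) and mask
#' (nearest-neighbour), then colour jitter to the image only.
#'
#' @param sample a `segmentation_sample`.
#' @param config an [augmentation_config()].
#' @param seed integer seed for the parameter draws.
#' @return an augmented `segmentation_sample` (mask still strictly binary).
#' @export
augment <- function(sample, config = augmentation_config(), seed = 1L) {
  stopifnot(inherits(config, "augmentation_config"))
  set.seed(as.integer(seed))
  h <- dim(sample$mask)[1]; w <- dim(sample$mask)[2]
  ang <- runif(1, config$rotation_degrees[1], config$rotation_degrees[2])
  ty <- runif(1, config$translation_fraction[1], config$translation_fraction[2]) * h
  tx <- runif(1, config$translation_fraction[1], config$translation_fraction[2]) * w
  sc <- runif(1, config$scale_factor[1], config$scale_factor[2])
  if (sc <= 0) stop("degenerate scale factor")
  fb <- runif(1, 1 - config$brightness, 1 + config$brightness)
  fc <- runif(1, 1 - config$contrast, 1 + config$contrast)
  fs <- runif(1, 1 - config$saturation, 1 + config$saturation)

  identity_geom <- ang == 0 && ty == 0 && tx == 0 && sc == 1
  if (identity_geom) {
    img <- sample$image
    msk <- sample$mask
  } else {
    co <- affine_source_coords(h, w, ang, ty, tx, sc)
    img <- sample$image
    for (c in 1:3) img[, , c] <- sample_plane_bilinear(sample$image[, , c], co$sy, co$sx)
    msk <- sample_plane_nearest(sample$mask, co$sy, co$sx)
  }
  if (fb != 1) img <- img * fb
  if (fc != 1) {
    mu <- mean(img)
    img <- (img - mu) * fc + mu
  }
  if (fs != 1) {
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    for (c in 1:3) img[, , c] <- gray + (img[, , c] - gray) * fs
  }
  if (fb != 1 || fc != 1 || fs != 1) img <- pmin(pmax(img, 0), 1)
  new_sample(img, msk, sample$seed)
}
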