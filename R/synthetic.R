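# Seeded generators for nucleus-like and vessel-like image/mask pairs.
#
# These emulate the two benchmark styles the network targets: many bright
# elliptical nuclei on a textured background, and thin branching vessels
# inside a bright circular fundus field. Every sample is fully determined by
# (spec, seed); the foreground fraction is kept inside the spec's target
# interval by bounded re-drawing with derived sub-seeds.

#' Sample specification for the synthetic generators
#'
#' @param height,width image size in pixels.
#' @param style `"nuclei"` or `"vessels"`.
#' @param object_count_range integer interval: number of ellipses (nuclei) or
#'   root branches (vessels).
#' @param size_range real interval in pixels: ellipse semi-axes (nuclei) or
#'   vessel stroke widths.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param target_foreground_fraction interval in (0, 1); samples are redrawn
#'   (bounded retries) until the mask fraction falls inside it.
#' @return a `sample_spec` list.
#' @export
sample_spec <- function(height = 64L, width = 64L,
                        style = c("nuclei", "vessels"),
                        object_count_range = NULL, size_range = NULL,
                        noise_sd = NULL,
                        target_foreground_fraction = NULL) {
  style <- match.arg(style)
  defaults <- if (style == "nuclei") {
    list(count = c(6L, 14L), size = c(3, 7), noise = 0.03, ff = c(0.06, 0.40))
  } else {
    list(count = c(2L, 4L), size = c(1.0, 2.5), noise = 0.02, ff = c(0.02, 0.25))
  }
  spec <- list(height = as.integer(height), width = as.integer(width),
               style = style,
               object_count_range = as.integer(object_count_range %||% defaults$count),
               size_range = as.numeric(size_range %||% defaults$size),
               noise_sd = as.numeric(noise_sd %||% defaults$noise),
               target_foreground_fraction =
                 as.numeric(target_foreground_fraction %||% defaults$ff))
  if (spec$height < 8L || spec$width < 8L) stop("image size too small")
  if (diff(spec$object_count_range) < 0 || diff(spec$size_range) < 0 ||
      diff(spec$target_foreground_fraction) < 0)
    stop("spec intervals must be nondecreasing")
  if (any(spec$target_foreground_fraction <= 0) ||
      any(spec$target_foreground_fraction >= 1))
    stop("target foreground fraction must lie in (0, 1)")
  if (spec$noise_sd < 0) stop("noise_sd must be nonnegative")
  class(spec) <- "sample_spec"
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_sample <- function(image, mask, seed) {
  stopifnot(identical(dim(image)[1:2], dim(mask)),
            all(mask %in% c(0, 1)))
  s <- list(image = image, mask = mask, seed = as.integer(seed))
  class(s) <- "segmentation_sample"
  s
}

# Smooth random background texture: coarse Gaussian field upsampled bilinearly.
random_texture <- function(h, w, cells = 8L, amplitude = 0.05) {
  coarse <- matrix(rnorm(cells * cells, 0, 1), cells, cells)
  gy <- seq(1, cells, length.out = h)
  gx <- seq(1, cells, length.out = w)
  y0 <- pmin(floor(gy), cells - 1L); x0 <- pmin(floor(gx), cells - 1L)
  fy <- gy - y0; fx <- gx - x0
  a <- coarse[cbind(rep(y0, w), rep(x0, each = h))]
  b <- coarse[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  cc <- coarse[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  d <- coarse[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  fym <- rep(fy, w); fxm <- rep(fx, each = h)
  v <- (1 - fym) * (1 - fxm) * a + fym * (1 - fxm) * b +
    (1 - fym) * fxm * cc + fym * fxm * d
  amplitude * matrix(v, h, w)
}

rasterize_ellipse <- function(h, w, cy, cx, a, b, theta) {
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(rep(seq_len(w), each = h), h, w) - cx
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

draw_nuclei_once <- function(spec) {
  h <- spec$height; w <- spec$width
  n_obj <- sample(spec$object_count_range[1]:spec$object_count_range[2], 1L)
  mask <- matrix(FALSE, h, w)
  shade <- matrix(0, h, w)
  for (i in seq_len(n_obj)) {
    a <- runif(1, spec$size_range[1], spec$size_range[2])
    b <- runif(1, spec$size_range[1], spec$size_range[2])
    m <- max(a, b)
    cy <- runif(1, 1 + m, h - m)
    cx <- runif(1, 1 + m, w - m)
    theta <- runif(1, 0, pi)
    e <- rasterize_ellipse(h, w, cy, cx, a, b, theta)
    mask <- mask | e
    shade[e] <- pmax(shade[e], runif(1, 0.30, 0.45))
  }
  list(mask = mask, shade = shade)
}

#' Generate a nucleus-like image/mask pair
#'
#' Bright ellipses (purple-tinted, H&E-like) on a dimmer textured background
#' with additive Gaussian noise; the mask is the exact union of the rasterized
#' ellipse interiors.
#'
#' @param spec a [sample_spec()] with `style = "nuclei"`.
#' @param seed integer; the same (spec, seed) always yields bit-identical
#'   output.
#' @param max_retries redraws allowed to land inside the target foreground
#'   fraction before erroring.
#' @return a `segmentation_sample`: `image` (H x W x 3 in `[0,1]`), `mask`
#'   (H x W in {0,1}), `seed`.
#' @export
generate_nuclei <- function(spec = sample_spec(style = "nuclei"), seed = 1L,
                            max_retries = 20L) {
  stopifnot(inherits(spec, "sample_spec"))
  if (spec$style != "nuclei") stop("spec style must be 'nuclei'")
  tf <- spec$target_foreground_fraction
  for (attempt in seq_len(max_retries)) {
    set.seed((as.integer(seed) * 131L + attempt - 1L) %% .Machine$integer.max)
    dr <- draw_nuclei_once(spec)
    ff <- mean(dr$mask)
    if (ff >= tf[1] && ff <= tf[2]) {
      h <- spec$height; w <- spec$width
      bg <- 0.35 + random_texture(h, w)
      base <- bg + dr$shade
      noise <- if (spec$noise_sd > 0) matrix(rnorm(h * w, 0, spec$noise_sd), h, w) else 0
      lum <- base + noise
      img <- array(0, c(h, w, 3))
      img[, , 1] <- lum * 0.85        # purple-ish foreground tint
      img[, , 2] <- lum * 0.70
      img[, , 3] <- lum
      img <- pmin(pmax(img, 0), 1)
      return(new_sample(img, dr$mask * 1, seed))
    }
  }
  stop("could not draw a nuclei sample inside the target foreground fraction (",
       tf[1], ", ", tf[2], ") after ", max_retries, " attempts")
}

# Quadratic Bezier points.
bezier_points <- function(p0, p1, p2, n = 64L) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

stamp_disc <- function(mask, cy, cx, r) {
  h <- nrow(mask); w <- ncol(mask)
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  if (y0 > y1 || x0 > x1) return(mask)
  ys <- y0:y1; xs <- x0:x1
  sub <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
  mask[ys, xs] <- mask[ys, xs] | sub
  mask
}

draw_vessels_once <- function(spec, branch_prob) {
  h <- spec$height; w <- spec$width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  radius <- 0.46 * min(h, w)
  n_roots <- sample(spec$object_count_range[1]:spec$object_count_range[2], 1L)
  mask <- matrix(FALSE, h, w)
  # each stack entry: start point, direction, remaining depth, width
  stack <- list()
  for (i in seq_len(n_roots)) {
    ang <- runif(1, 0, 2 * pi)
    stack[[length(stack) + 1L]] <- list(
      p = c(cy, cx), dir = ang, depth = 4L,
      width = runif(1, mean(spec$size_range), spec$size_range[2]))
  }
  seg_len <- radius / 2.2
  while (length(stack)) {
    s <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    dir <- s$dir + runif(1, -0.5, 0.5)
    p2 <- s$p + seg_len * c(sin(dir), cos(dir))
    ctrl <- (s$p + p2) / 2 + runif(2, -seg_len / 4, seg_len / 4)
    pts <- bezier_points(s$p, ctrl, p2, n = max(16L, ceiling(seg_len * 2)))
    wts <- seq(s$width, max(spec$size_range[1], s$width * 0.8),
               length.out = nrow(pts))
    for (i in seq_len(nrow(pts))) {
      if ((pts[i, 1] - cy)^2 + (pts[i, 2] - cx)^2 > radius^2) next
      mask <- stamp_disc(mask, pts[i, 1], pts[i, 2], wts[i] / 2)
    }
    if (s$depth > 1L &&
        (p2[1] - cy)^2 + (p2[2] - cx)^2 <= radius^2 &&
        tail(wts, 1) >= spec$size_range[1]) {
      if (runif(1) < branch_prob) {
        spread <- runif(1, 0.3, 0.7)
        for (sgn in c(-1, 1))
          stack[[length(stack) + 1L]] <- list(
            p = p2, dir = dir + sgn * spread, depth = s$depth - 1L,
            width = tail(wts, 1) * runif(1, 0.75, 0.95))
      } else {
        stack[[length(stack) + 1L]] <- list(
          p = p2, dir = dir, depth = s$depth - 1L, width = tail(wts, 1))
      }
    }
  }
  field <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`) <= radius^2
  list(mask = mask & field, field = field)
}

#' Generate a vessel-like image/mask pair
#'
#' A bright circular field on a dark background with a random branching tree
#' of smooth curves (quadratic Bezier segments) of tapering width; the mask is
#' the union of the stroked curves clipped to the field.
#'
#' @param spec a [sample_spec()] with `style = "vessels"`.
#' @param seed integer seed (deterministic per (spec, seed)).
#' @param branch_prob probability that a segment splits into two children.
#' @param max_retries redraws allowed to land inside the target foreground
#'   fraction.
#' @return a `segmentation_sample`.
#' @export
generate_vessels <- function(spec = sample_spec(style = "vessels"), seed = 1L,
                             branch_prob = 0.6, max_retries = 20L) {
  stopifnot(inherits(spec, "sample_spec"))
  if (spec$style != "vessels") stop("spec style must be 'vessels'")
  tf <- spec$target_foreground_fraction
  for (attempt in seq_len(max_retries)) {
    set.seed((as.integer(seed) * 131L + attempt - 1L) %% .Machine$integer.max)
    dr <- draw_vessels_once(spec, branch_prob)
    ff <- mean(dr$mask)
    if (ff >= tf[1] && ff <= tf[2]) {
      h <- spec$height; w <- spec$width
      img <- array(0, c(h, w, 3))
      base_r <- 0.12 + 0.50 * dr$field + random_texture(h, w, amplitude = 0.03)
      base_g <- 0.08 + 0.28 * dr$field + random_texture(h, w, amplitude = 0.02)
      base_b <- 0.06 + 0.16 * dr$field
      # vessels darker than the surrounding field
      base_r[dr$mask] <- base_r[dr$mask] - 0.30
      base_g[dr$mask] <- base_g[dr$mask] - 0.18
      noise <- if (spec$noise_sd > 0) matrix(rnorm(h * w, 0, spec$noise_sd), h, w) else 0
      img[, , 1] <- base_r + noise
      img[, , 2] <- base_g + noise
      img[, , 3] <- base_b + noise
      img <- pmin(pmax(img, 0), 1)
      return(new_sample(img, dr$mask * 1, seed))
    }
  }
  stop("could not draw a vessel sample inside the target foreground fraction (",
       tf[1], ", ", tf[2], ") after ", max_retries, " attempts")
}

#' Generate a seeded dataset
#'
#' @param spec a [sample_spec()].
#' @param n number of samples.
#' @param seed_start first seed; sample i uses `seed_start + i - 1`, so
#'   train/test splits from disjoint seed ranges never share a sample.
#' @param ... passed to the style's generator.
#' @return list of `segmentation_sample`s.
#' @export
generate_dataset <- function(spec, n, seed_start = 1L, ...) {
  lapply(seq_len(n), function(i) {
    gen <- if (spec$style == "nuclei") generate_nuclei else generate_vessels
    gen(spec, seed = seed_start + i - 1L, ...)
  })
}

#' @importFrom utils tail
NULL
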