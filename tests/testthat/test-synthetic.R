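# Synthetic nucleus/vessel generators, augmentation, dataset I/O.

test_that("generation is bit-identical per (spec, seed) and varies across seeds", {
  for (style in c("nuclei", "vessels")) {
    spec <- sample_spec(48, 48, style)
    gen <- if (style == "nuclei") generate_nuclei else generate_vessels
    s1 <- gen(spec, seed = 7)
    s2 <- gen(spec, seed = 7)
    expect_identical(s1$image, s2$image)
    expect_identical(s1$mask, s2$mask)
    s3 <- gen(spec, seed = 8)
    expect_false(identical(s1$mask, s3$mask))
  }
})

test_that("samples satisfy their own spec invariants", {
  spec <- sample_spec(48, 48, "nuclei")
  tf <- spec$target_foreground_fraction
  for (seed in 1:30) {
    s <- generate_nuclei(spec, seed)
    expect_identical(dim(s$image), c(48L, 48L, 3L))
    expect_true(all(s$mask %in% c(0, 1)))
    expect_true(all(s$image >= 0 & s$image <= 1))
    ff <- mean(s$mask)
    expect_true(ff >= tf[1] && ff <= tf[2])
  }
})

test_that("ellipse rasterization matches a pixel-loop oracle", {
  set.seed(40)
  for (rep in 1:5) {
    h <- 32; w <- 40
    cy <- runif(1, 8, 24); cx <- runif(1, 8, 32)
    a <- runif(1, 2, 6); b <- runif(1, 2, 6); th <- runif(1, 0, pi)
    m <- axunet:::rasterize_ellipse(h, w, cy, cx, a, b, th)
    for (y in seq_len(h)) for (x in seq_len(w)) {
      u <- (x - cx) * cos(th) + (y - cy) * sin(th)
      v <- -(x - cx) * sin(th) + (y - cy) * cos(th)
      expect_identical(m[y, x], (u / a)^2 + (v / b)^2 <= 1)
    }
  }
  # single noise-free ellipse: mask area equals the rasterized count
  spec <- sample_spec(48, 48, "nuclei", object_count_range = c(1L, 1L),
                      size_range = c(5, 5), noise_sd = 0,
                      target_foreground_fraction = c(0.005, 0.2))
  s <- generate_nuclei(spec, seed = 3)
  # a=b=5 circle: discrete area is within 2 px of pi*25 for any centre
  expect_true(abs(sum(s$mask) - pi * 25) < 8)
  expect_equal(oracle_n_components(s$mask == 1), 1L)
})

test_that("vessel masks stay inside the field and form one component without branching", {
  spec <- sample_spec(48, 48, "vessels", object_count_range = c(1L, 1L),
                      target_foreground_fraction = c(0.005, 0.3))
  cy <- (48 + 1) / 2; radius <- 0.46 * 48
  for (seed in 1:5) {
    s <- generate_vessels(spec, seed, branch_prob = 0)
    idx <- which(s$mask == 1, arr.ind = TRUE)
    expect_true(all((idx[, 1] - cy)^2 + (idx[, 2] - cy)^2 <= radius^2))
    expect_equal(oracle_n_components(s$mask == 1), 1L)
  }
  s <- generate_vessels(sample_spec(48, 48, "vessels"), 1)
  expect_true(all(s$mask %in% c(0, 1)))
})

test_that("augmentation respects identity, 90-degree rotation, and binarity", {
  spec <- sample_spec(48, 48, "nuclei")
  s <- generate_nuclei(spec, 5)
  ident <- augmentation_config(rotation_degrees = c(0, 0),
                               translation_fraction = c(0, 0),
                               scale_factor = c(1, 1),
                               brightness = 0, contrast = 0, saturation = 0)
  a <- augment(s, ident, seed = 1)
  expect_identical(a$image, s$image)
  expect_identical(a$mask, s$mask)

  rot90 <- augmentation_config(rotation_degrees = c(90, 90),
                               translation_fraction = c(0, 0),
                               scale_factor = c(1, 1),
                               brightness = 0, contrast = 0, saturation = 0)
  a90 <- augment(s, rot90, seed = 1)
  n <- 48
  expect_equal(a90$mask, t(s$mask[n:1, ]))   # exact index permutation

  jitter <- augmentation_config()
  for (seed in 1:5) {
    aj <- augment(s, jitter, seed = seed)
    expect_true(all(aj$mask %in% c(0, 1)))
    expect_true(all(aj$image >= 0 & aj$image <= 1))
  }
  expect_error(augmentation_config(scale_factor = c(-1, 1)), "positive")
})

test_that("datasets round-trip through PNG exactly (masks) and to 8 bits (images)", {
  spec <- sample_spec(32, 32, "nuclei")
  samples <- generate_dataset(spec, 5, seed_start = 50)
  dir <- file.path(tempdir(), "axunet-ds-test")
  unlink(dir, recursive = TRUE)
  write_dataset(samples, dir, spec = spec)
  back <- read_dataset(dir)
  expect_length(back, 5)
  for (i in 1:5) {
    expect_identical(back[[i]]$mask, samples[[i]]$mask)
    expect_lte(max(abs(back[[i]]$image - samples[[i]]$image)), 1 / 255)
    expect_identical(back[[i]]$seed, samples[[i]]$seed)
  }
  # integrity: image without mask
  file.remove(file.path(dir, "masks", "sample_0002.png"))
  err <- expect_error(read_dataset(dir), "integrity")
  expect_match(conditionMessage(err), "sample_0002")
  unlink(dir, recursive = TRUE)
})
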