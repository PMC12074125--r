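# On-disk dataset layout:
#   <root>/images/<id>.png   8-bit RGB
#   <root>/masks/<id>.png    8-bit single-channel, values {0, 255}
#   <root>/manifest.json     ids, generating spec and seeds (when known)

#' Write a dataset of samples to disk
#'
#' @param samples list of `segmentation_sample`s.
#' @param directory target directory (created if needed).
#' @param ids optional character ids; default `sample_0001`, ...
#' @param spec optional [sample_spec()] recorded in the manifest.
#' @return `directory`, invisibly.
#' @export
write_dataset <- function(samples, directory, ids = NULL, spec = NULL) {
  if (is.null(ids))
    ids <- sprintf("sample_%04d", seq_along(samples))
  dir.create(file.path(directory, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(directory, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    png::writePNG(s$image, file.path(directory, "images", paste0(ids[i], ".png")))
    png::writePNG(s$mask, file.path(directory, "masks", paste0(ids[i], ".png")))
  }
  manifest <- list(ids = ids,
                   seeds = vapply(samples, function(s) s$seed %||% NA_integer_,
                                  integer(1)),
                   spec = if (!is.null(spec)) unclass(spec) else NULL)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param directory dataset root.
#' @return list of `segmentation_sample`s (masks binarized at 0.5).
#' @export
read_dataset <- function(directory) {
  img_dir <- file.path(directory, "images")
  msk_dir <- file.path(directory, "masks")
  if (!dir.exists(img_dir) || !dir.exists(msk_dir))
    stop("not a dataset directory (missing images/ or masks/): ", directory)
  img_files <- sort(list.files(img_dir, pattern = "\\.png$"))
  if (!length(img_files)) stop("no images found in ", img_dir)
  manifest_path <- file.path(directory, "manifest.json")
  seeds <- NULL
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (!is.null(man$ids) && length(man$ids) == length(img_files))
      seeds <- man$seeds
  }
  lapply(seq_along(img_files), function(i) {
    f <- img_files[i]
    mf <- file.path(msk_dir, f)
    if (!file.exists(mf))
      stop("dataset integrity error: image '", f, "' has no mask file '", mf, "'")
    img <- png::readPNG(file.path(img_dir, f))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
    msk <- png::readPNG(mf)
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    sd <- if (!is.null(seeds) && is.finite(seeds[i])) as.integer(seeds[i]) else NA_integer_
    new_sample(img, (msk >= 0.5) * 1, sd)
  })
}
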