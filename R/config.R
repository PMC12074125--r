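# YAML configuration round-trip: a file with `network:` and `training:`
# sections mapping directly onto network_config() / training_config() keys.

#' Read a YAML run configuration
#'
#' @param path YAML file with optional `network:` and `training:` sections.
#' @return list with elements `network` ([network_config()]) and `training`
#'   ([training_config()]).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  net <- do.call(network_config, raw$network %||% list())
  aug <- NULL
  tr_raw <- raw$training %||% list()
  if (!is.null(tr_raw$augment_config))
    aug <- do.call(augmentation_config, tr_raw$augment_config)
  tr_raw$augment_config <- aug
  tr <- do.call(training_config, tr_raw)
  list(network = net, training = tr)
}

#' Write a YAML run configuration
#'
#' @param config list with `network` and/or `training` entries as returned by
#'   [read_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- list()
  if (!is.null(config$network)) out$network <- unclass(config$network)
  if (!is.null(config$training)) {
    tr <- unclass(config$training)
    if (!is.null(tr$augment_config)) tr$augment_config <- unclass(tr$augment_config)
    out$training <- tr
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON capture of the configuration, seed, and library versions, for
#' reproducibility of a training run.
#'
#' @param config list with `network`/`training` entries.
#' @param path output JSON file.
#' @param extra optional named list appended verbatim.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, path, extra = list()) {
  man <- c(list(
    network = unclass(config$network),
    training = unclass(config$training),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("axunet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
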