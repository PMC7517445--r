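#' Load a YAML run configuration
#'
#' The file may contain `blocks`, `network`, `train` and `data` sections;
#' every field defaults to the package defaults ([block_config()],
#' [network_config()], [train_config()]). Unknown fields are rejected.
#'
#' @param path YAML file path.
#' @param overrides named list applied on top of the file (e.g. flag
#'   values), using `section.field` names.
#' @return list with elements `network` (a `network_config`), `train`
#'   (a `train_config`) and `data` (a plain list).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop(sprintf("override '%s' is not of the form section.field", nm))
    raw[[parts[1]]][[parts[2]]] <- overrides[[nm]]
  }
  known <- c("blocks", "network", "train", "data")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop(sprintf("unknown config section(s): %s", paste(bad, collapse = ", ")))
  blk <- do.call(block_config, raw$blocks %||% list())
  net_args <- raw$network %||% list()
  net_args$blocks <- blk
  list(network = do.call(network_config, net_args),
       train = do.call(train_config, raw$train %||% list()),
       data = raw$data %||% list())
}

#' Write a JSON run manifest
#'
#' Records the configuration, seed and session package versions alongside
#' a run's artifacts so results can be traced back to their inputs.
#'
#' @param path output file.
#' @param config list as returned by [load_config()].
#' @param seed the run seed.
#' @param extra optional named list of additional fields.
#' @export
write_manifest <- function(path, config, seed, extra = list()) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing a run manifest requires the 'jsonlite' package")
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  manifest <- c(list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    package_version = as.character(utils::packageVersion("acaunet")),
    r_version = R.version.string,
    config = strip(config)), extra)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}
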