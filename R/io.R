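#' Load a configuration file
#'
#' Reads a flat JSON or YAML configuration whose keys match the parameter
#' fields of \code{\link{model_parameters}} and applies overrides on top
#' (precedence: overrides > file > defaults).  An empty file yields the
#' defaults.
#'
#' @param path path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @param overrides named list applied after the file values.
#' @return a validated \code{memorg_params} object.
#' @export
load_config <- function(path, overrides = list()) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configurations",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else jsonlite::fromJSON(txt)
  }
  if (is.null(vals)) vals <- list()
  vals[names(overrides)] <- overrides
  model_parameters(vals)
}

#' Write a resolved configuration
#'
#' Serializes a parameter set to JSON so that
#' \code{load_config(write_config(p, f))} round-trips to an identical
#' parameter set.
#'
#' @param params a \code{memorg_params}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Write simulation outputs with a run manifest
#'
#' Writes the trajectory samples as CSV (columns \code{t, F1, F2, FB, w11,
#' w22, w21, w12, wB_mean, inh_11, inh_22, inh_12, inh_21}) together with a
#' JSON sidecar carrying the resolved parameters, seed and protocol, and a
#' manifest listing every file written.  Reruns with the same seed produce
#' byte-identical CSVs.
#'
#' @param trajectory a \code{memorg_trajectory}.
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return the manifest (named list), invisibly.
#' @export
write_trajectory <- function(trajectory, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) && !force)
    stop("output directory exists and is not empty; use force = TRUE",
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "trajectory.csv")
  utils::write.csv(trajectory$samples, csv, row.names = FALSE)
  sidecar <- file.path(dir, "run.json")
  jsonlite::write_json(list(
    params = unclass(trajectory$params),
    seed = trajectory$seed,
    protocol = lapply(trajectory$protocol, unclass),
    equilibrium = trajectory$equilibrium,
    final_averages = as.list(trajectory$final_averages),
    package_version = as.character(utils::packageVersion("memorg"))
  ), sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  manifest <- list(
    files = c(basename(csv), basename(sidecar)),
    seed = trajectory$seed,
    written = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write a fixed-point set as JSON
#'
#' @param fps a \code{memorg_fps} (see \code{\link{find_fixed_points}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fixed_points <- function(fps, path) {
  jsonlite::write_json(list(
    input = attr(fps, "input"),
    bistable = attr(fps, "bistable"),
    points = as.data.frame(fps)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
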