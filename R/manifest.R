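#' Build a run manifest
#'
#' Captures everything needed to reproduce a run exactly: the configuration,
#' the seed, md5 checksums of the input files, package and R versions,
#' wall-clock time and the per-window construction summary.
#'
#' @param config the `cfhlc_config` (or any list of settings) used.
#' @param inputs character vector of input file paths (checksummed if they
#'   exist).
#' @param window_log optional per-window tibble (attribute `window_log` of a
#'   learned forest).
#' @param elapsed_sec wall-clock seconds.
#' @return A manifest list, serializable with [write_manifest()].
#' @export
run_manifest <- function(config, inputs = character(), window_log = NULL,
                         elapsed_sec = NA_real_) {
  sums <- if (length(inputs)) {
    existing <- inputs[file.exists(inputs)]
    as.list(tools::md5sum(existing))
  } else {
    list()
  }
  list(
    config = unclass(config),
    input_checksums = sums,
    versions = list(
      package = as.character(utils::packageVersion("fhlcforest")),
      r = paste(R.version$major, R.version$minor, sep = ".")
    ),
    elapsed_sec = elapsed_sec,
    windows = if (!is.null(window_log)) as.list(window_log) else NULL,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Write a manifest as JSON
#'
#' @param manifest list from [run_manifest()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Metrics report for a learned forest
#'
#' Convenience wrapper collecting the headline evaluation metrics in one
#' tibble: dimension reduction rate, entropy compression rate, tree count,
#' latent count, maximum layer and percentage variable reduction.
#'
#' @param forest an `fhlc_forest`.
#' @param data the [snp_matrix()] it was learned from.
#' @return A one-row tibble.
#' @export
forest_metrics <- function(forest, data) {
  g <- glance(forest)
  g$ecr <- entropy_compression_rate(forest, data)
  g
}
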