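#' Write a provenance record
#'
#' Serialises the run configuration, seed, package and R versions, and a
#' timestamp to JSON next to a pipeline's outputs.
#'
#' @param path Output JSON path.
#' @param config Named list of run parameters.
#' @param seed Integer seed used for the run.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config = list(), seed = NULL) {
  rec <- list(
    package = "metameta",
    version = as.character(utils::packageVersion("metameta")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
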