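#' Write a JSON sidecar recording run provenance
#'
#' Records the package version, R version, parameters and seed of a run
#' next to its outputs, so any stochastic result can be regenerated.
#'
#' @param path Output JSON path.
#' @param params Named list of parameters (include `seed` for stochastic
#'   runs).
#' @return `path`, invisibly.
#' @export
write_run_meta <- function(path, params) {
  meta <- list(
    package = "poolcnv",
    version = as.character(utils::packageVersion("poolcnv")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
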