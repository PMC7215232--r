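#' Package default constants
#'
#' Reads the versioned defaults file shipped with the package
#' (`extdata/defaults.yaml`): thermophysical constants of dry air at 0 degC,
#' strawberry properties, transpiration parameters, correlation coefficients
#' and the calibrated package/zone geometry. All property constructors pull
#' their default values from here, so a single edited copy of the file can
#' redefine the study conditions.
#'
#' @param path Optional path to an alternative defaults file.
#' @return Nested list mirroring the YAML structure; each leaf holds
#'   `value`, `units` and optionally `note`.
#' @export
#' @examples
#' precool_defaults()$fruit$k_p$value
precool_defaults <- function(path = NULL) {
  shipped <- is.null(path)
  if (shipped) {
    if (!is.null(.precool_cache$defaults)) {
      return(.precool_cache$defaults)
    }
    path <- system.file("extdata", "defaults.yaml", package = "precoolr")
  }
  stopifnot(nzchar(path), file.exists(path))
  defs <- yaml::read_yaml(path)
  if (is.null(defs$schema_version)) {
    stop("defaults file has no schema_version")
  }
  if (shipped) .precool_cache$defaults <- defs
  defs
}

.precool_cache <- new.env(parent = emptyenv())

# shorthand: numeric value of one defaults entry
.def <- function(group, name) {
  precool_defaults()[[group]][[name]]$value
}
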