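# YAML run configuration for scripted use (CLI and batch runs).

#' Read a YAML run configuration
#'
#' Recognized top-level keys (all optional): \code{dataset} (path),
#' \code{task_kind}, \code{split} (method/ratios/seed), \code{model}
#' (multiview_config arguments), \code{optim} (optim_config arguments),
#' \code{seeds}, \code{synthesis} (synthesis_spec arguments).
#'
#' @param path YAML file.
#' @return named list of configuration blocks.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  yaml::read_yaml(path)
}

#' Build a synthesis spec from a config block
#' @param block list of \code{\link{synthesis_spec}} arguments.
#' @export
synthesis_spec_from_config <- function(block) {
  do.call(synthesis_spec, block %||% list())
}
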