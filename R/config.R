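# YAML round-trip for model configurations: bank, weights, participant and
# interaction sections, with the packaged reference values as defaults.

#' Default model configuration
#'
#' @return Nested list with `bank`, `weights`, `participant`, `interaction`
#'   and `protocol` sections holding the packaged reference parameters.
#' @export
default_model_config <- function() {
  bs <- bank_spec()
  pp <- participant_params()
  ip <- interaction_params()
  list(bank = unclass(bs),
       weights = as.list(default_weight_coefficients()),
       participant = unclass(pp),
       interaction = unclass(ip),
       protocol = list(n_windows = 3, grid_range = c(-2, 10), grid_n = 512))
}

#' Read / write a model configuration as YAML
#'
#' Sections missing from the file fall back to the packaged defaults.
#'
#' @param path File path.
#' @param config Nested list as produced by [default_model_config()].
#' @return `read_model_config()` returns the merged configuration list;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("The yaml package is required for configuration files.")
  }
  user <- yaml::read_yaml(path)
  cfg <- default_model_config()
  for (sec in intersect(names(user), names(cfg))) {
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  cfg
}

#' @rdname read_model_config
#' @export
write_model_config <- function(config = default_model_config(), path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("The yaml package is required for configuration files.")
  }
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Instantiate model objects from a configuration
#'
#' @param config Configuration list from [read_model_config()] or
#'   [default_model_config()].
#' @return List with `bank`, `participant`, `interaction`, `grid`.
#' @export
build_model <- function(config = default_model_config()) {
  bs <- do.call(bank_spec, config$bank)
  b <- setNames(as.numeric(config$weights), names(config$weights))
  list(bank = build_bank(bs, b),
       participant = do.call(participant_params, config$participant),
       interaction = do.call(interaction_params, config$interaction),
       grid = speed_grid(config$protocol$grid_range, config$protocol$grid_n))
}
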