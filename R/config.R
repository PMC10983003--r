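# Run configuration: one flat place for every tunable the pipeline reads.
# Configurations are plain named lists; files are YAML with the same keys.

#' Default pipeline configuration
#'
#' @param ... Named overrides, possibly nested (e.g. `scf = list(tol = 1e-10)`).
#' @return Named list with components `scf` (`tol`, `max_iter`, `damping`),
#'   `overlap` (`method`: "exact" or "spline"), `lc` (`slope`,
#'   `intercept`), `classify` (`level`, `use_lc`, `threshold`),
#'   `cutoff_scale`, `valence_table` (path or NULL for the packaged one).
#' @export
#' @examples
#' cfg <- pppConfig(lc = list(slope = 0.6))
#' cfg$lc$slope
pppConfig <- function(...) {
  cfg <- list(
    scf = list(tol = 1e-8, max_iter = 200, damping = 0.5),
    overlap = list(method = "exact"),
    lc = list(slope = 0.53, intercept = -0.15),
    classify = list(level = "gap_cis_dsp", use_lc = FALSE, threshold = 0),
    cutoff_scale = 1.15,
    valence_table = NULL
  )
  .merge_config(cfg, list(...))
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a configuration file
#'
#' YAML file whose keys mirror [pppConfig()]; unspecified keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @export
readConfig <- function(path) {
  .merge_config(pppConfig(), yaml::read_yaml(path))
}

#' Write a configuration file
#'
#' @param config Configuration list.
#' @param path Output YAML path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.config_table <- function(config) {
  if (is.null(config$valence_table)) defaultValenceTable()
  else valenceStateTable(config$valence_table)
}
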