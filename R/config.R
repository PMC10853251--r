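## Pipeline configuration: a validated named list that round-trips through
## YAML losslessly; unknown keys are rejected.

.config_defaults <- function() {
  list(
    fs = 1000,
    duration_s = 30,
    wavelet = "sym4",
    levels = 5:10,
    window_s = 8,
    crossfade_s = 0.25,
    resp_hp = c(0.35, 0.55),
    refractory_s = 0.3,
    threshold_k = 3,
    min_gap_frac = 0.55,
    search_s = 0.25,
    prom_frac = 0.1,
    dtw_band_s = 0.1,
    dtw_max_medoid = 25,
    latent_loading = 0.5,
    cohort_n = 541,
    class_ratio = c(337, 204),
    cv_folds = 5,
    models = CLASSIFIER_MODELS,
    n_subjects_per_class = 3
  )
}

#' Build a pipeline configuration
#'
#' Starts from the package defaults and applies the supplied overrides;
#' unknown keys are rejected.
#'
#' @param ... named overrides of default keys.
#' @return a named list of class "bcg_config".
#' @export
#' @examples
#' cfg <- bcgConfig(fs = 500, duration_s = 20)
bcgConfig <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) || is.null(names(over)) || any(names(over) == ""))
      stop("configuration error: unknown config key(s): ",
           paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "bcg_config")
}

#' Write / read a configuration as YAML
#'
#' @param config a configuration from \code{\link{bcgConfig}}.
#' @param path YAML file path.
#' @return \code{readConfig} returns the validated configuration.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(bcgConfig, raw)
}

## short stable hash of the resolved configuration (for report logging)
.config_hash <- function(config) {
  s <- paste(vapply(names(config), function(k)
    paste0(k, "=", paste(format(config[[k]], digits = 15), collapse = ",")),
    character(1)), collapse = ";")
  v <- utf8ToInt(s)
  h <- 5381
  for (c in v) h <- (h * 33 + c) %% 2147483647
  sprintf("%08x", h)
}
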