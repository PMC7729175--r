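#' Default run configuration
#'
#' One document holding every tunable of the pipeline, overridable from a
#' YAML file or CLI flags. Unknown keys are rejected so typos cannot
#' silently fall back to defaults.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    version = 1L,
    bands = list(classify = c(4, 14), artifact = c(20, 40),
                 broadband = c(4, 40)),
    filter_order = 256L,
    epoch_ms = 800,
    decimation = 4L,
    artifact = list(vpp_max = 200, sigma_max = 50, ratio_max = 0.7),
    n_w = 4L,
    stepwise = stepwise_config(),
    controller = unclass(controller_config()),
    calibration = calibration_config(),
    simulator = unclass(sim_params()),
    evaluation = list(cv_folds = 5L, permutations = 1000L)
  )
}

merge_config <- function(defaults, override, path = "") {
  if (!is.list(override)) return(override)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop_validation(sprintf("unknown config key(s): %s",
                            paste0(path, unknown, collapse = ", ")))
  }
  for (k in names(override)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(override[[k]])) {
      merge_config(defaults[[k]], override[[k]], paste0(path, k, "."))
    } else {
      override[[k]]
    }
  }
  defaults
}

#' Load a YAML run configuration
#'
#' @param path YAML file; keys override [default_config()] values. Unknown
#'   keys raise a validation error.
#' @return Full configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Hash of the effective configuration
#'
#' MD5 over the canonical JSON serialization; echoed into every output
#' bundle so results can be regenerated.
#'
#' @param config Configuration list.
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}
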