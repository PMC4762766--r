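# Scenario (de)serialization: JSON or YAML configuration files with a
# strict key schema.  Unknown keys are rejected so that typos in a config
# never silently fall back to defaults.

.idm_config_keys <- c(
  "disease", "n_subjects", "entry_age_min", "entry_age_max",
  "followup_years", "visit_interval", "ltfu_rate",
  "prevalence_env", "prevalence_gen", "misclass_env", "misclass_gen",
  "hr_env", "hr_gen", "hr_gxe", "frailty_sd", "alpha",
  "transitions")

#' Read and write scenario configuration files
#'
#' Scenarios round-trip through flat JSON or YAML files (chosen by file
#' extension) holding exactly the fields of [scenario()].  The optional
#' `transitions` key is a nested mapping with `healthy_to_diseased` /
#' `healthy_to_dead` entries, each a `(scale, shape)` pair, and overrides
#' the disease preset.  Unknown keys raise an error naming the offending
#' field.  JSON output preserves full double precision, so a written
#' scenario reads back bit-identically.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @param scenario An [scenario()] object.
#' @return `read_scenario_config()` returns an `idm_scenario`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- switch(.config_format(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = yaml::read_yaml(path))
  if (!is.list(cfg)) stop("config must be a mapping of scenario fields",
                          call. = FALSE)
  unknown <- setdiff(names(cfg), .idm_config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$transitions)) {
    tr <- cfg$transitions
    need <- c("healthy_to_diseased", "healthy_to_dead")
    if (!is.list(tr) || !all(need %in% names(tr))) {
      stop("config key `transitions` must contain ",
           paste(need, collapse = " and "), call. = FALSE)
    }
    cfg$transitions <- transition_set(
      healthy_to_diseased = weibull_params(tr$healthy_to_diseased$scale,
                                           tr$healthy_to_diseased$shape),
      healthy_to_dead = weibull_params(tr$healthy_to_dead$scale,
                                       tr$healthy_to_dead$shape))
  }
  do.call(scenario, cfg)
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "idm_scenario"))
  cfg <- unclass(scenario)
  cfg$transitions <- list(
    healthy_to_diseased = unclass(cfg$transitions$healthy_to_diseased),
    healthy_to_dead = unclass(cfg$transitions$healthy_to_dead))
  switch(.config_format(path),
         json = jsonlite::write_json(cfg, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         yaml = yaml::write_yaml(cfg, path, precision = 15L))
  invisible(path)
}

.config_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") return("json")
  if (ext %in% c("yaml", "yml")) return("yaml")
  stop("config file must end in .json, .yaml or .yml: ", path, call. = FALSE)
}
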