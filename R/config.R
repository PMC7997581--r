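#' Run configuration, optionally from a YAML file
#'
#' Returns the run configuration merged over the package defaults.
#' Recognised keys: `temperature_K` (298.15), `energy_unit` (`"kcal_mol"`;
#' also `"kj_mol"`, `"hartree"`), `energy_window` (3.0, in `energy_unit`),
#' `carbonyl_policy` (`"tms"`), `standards` (list with `tms_sigma`,
#' `benzene_sigma`, `benzene_delta_exp` = 128.37 -- the sigmas are
#' level-of-theory specific and have no default), `metrics`
#' (`c("mae_dddelta", "avg_mae")`), `max_sets` (8), `tie_tol` (1e-9).
#'
#' @param path Optional path to a YAML file; keys present there override the
#'   defaults.
#' @return A named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    temperature_K = 298.15,
    energy_unit = "kcal_mol",
    energy_window = 3.0,
    carbonyl_policy = "tms",
    standards = list(tms_sigma = NULL, benzene_sigma = NULL,
                     benzene_delta_exp = 128.37),
    metrics = c("mae_dddelta", "avg_mae"),
    max_sets = 8,
    tie_tol = 1e-9
  )
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  if (!is.list(user)) abort("config file must hold a YAML mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    warn(sprintf("ignoring unknown config key(s): %s",
                 paste(unknown, collapse = ", ")))
    user <- user[intersect(names(user), names(defaults))]
  }
  cfg <- modifyList(defaults, user)
  if (!cfg$energy_unit %in% names(GAS_CONSTANT)) {
    abort(sprintf("unknown energy_unit \"%s\"; use one of %s", cfg$energy_unit,
                  paste(names(GAS_CONSTANT), collapse = ", ")))
  }
  if (!cfg$carbonyl_policy %in% c("tms", "benzene")) {
    abort("carbonyl_policy must be \"tms\" or \"benzene\"")
  }
  cfg
}
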