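# Run configuration: one validated container for everything a full run
# needs, loadable from JSON or YAML.

CONFIG_KEYS <- c("targets", "stock", "budget_t_ref", "budget_p_ref",
                 "vial", "constraints", "geometry", "fluid",
                 "analytes", "noise", "replicates", "seed",
                 "loaded_volume", "vial_capacity")
CONSTRAINT_KEYS <- c("p_min", "p_max", "p_quantum", "t_default", "t_max",
                     "t_quantum")
GEOMETRY_KEYS <- c("total_length_cm", "effective_length_cm", "id_um")
FLUID_KEYS <- c("viscosity_mpas", "name")

#' Build a validated run configuration
#'
#' The default is the standard PCR-vial study: six targets from 6.25 to
#' 75 ug/mL plus the undiluted 100 ug/mL working solution, a 10 min /
#' 20 psi reference transfer, triplicate runs.
#'
#' @param targets Target concentrations, ug/mL.
#' @param stock Working-solution concentration, ug/mL.
#' @param budget_t_ref,budget_p_ref Reference transfer time (min) and
#'   pressure (psi) defining the budget; see [reference_budget()].
#' @param vial `"pcr"` or `"nano"`; selects the constraint profile and
#'   sensible volume defaults unless overridden.
#' @param constraints,geometry,fluid,analytes,noise Optional component
#'   overrides (objects from their respective constructors).
#' @param replicates Runs per level.
#' @param seed Integer seed.
#' @param loaded_volume,vial_capacity Source load and collection capacity,
#'   uL.
#' @return An object of class `ahmt_config`.
#' @export
ahmt_config <- function(targets = c(6.25, 12.5, 25, 37.5, 50, 75, 100),
                        stock = 100,
                        budget_t_ref = 10, budget_p_ref = NULL,
                        vial = c("pcr", "nano"),
                        constraints = NULL, geometry = capillary_geometry(),
                        fluid = ahmt::fluid(), analytes = default_analytes(),
                        noise = noise_model(), replicates = 3, seed = 42,
                        loaded_volume = 200, vial_capacity = NULL) {
  vial <- match.arg(vial)
  if (is.null(budget_p_ref)) budget_p_ref <- if (vial == "pcr") 20 else 2
  if (is.null(constraints))
    constraints <- if (vial == "pcr") pcr_constraints() else nano_constraints()
  if (is.null(vial_capacity)) vial_capacity <- if (vial == "pcr") 200 else 50
  stopifnot(length(targets) >= 1, all(targets > 0), stock > 0,
            replicates >= 1)
  structure(list(targets = targets, stock = stock,
                 budget = reference_budget(budget_t_ref, budget_p_ref),
                 vial = vial, constraints = constraints,
                 geometry = geometry, fluid = fluid,
                 analytes = analytes, noise = noise,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 loaded_volume = loaded_volume,
                 vial_capacity = vial_capacity),
            class = "ahmt_config")
}

#' Read a run configuration from JSON or YAML
#'
#' Recognized keys: `targets`, `stock`, `budget_t_ref`, `budget_p_ref`,
#' `vial`, `replicates`, `seed`, `loaded_volume`, `vial_capacity`;
#' `constraints` (sub-keys `p_min`, `p_max`, `p_quantum`, `t_default`,
#' `t_max`, `t_quantum`); `geometry` (`total_length_cm`,
#' `effective_length_cm`, `id_um`); `fluid` (`viscosity_mpas`, `name`);
#' `noise` (`area_cv`, `migration_drift_cv`, `baseline_sd`);
#' `analytes` (list of `name`, `migration_time`, `response_factor`,
#' `peak_width_sigma`). Unknown keys are rejected by name.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An [ahmt_config()].
#' @export
read_ahmt_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  check_keys <- function(got, allowed, where) {
    bad <- setdiff(names(got), allowed)
    if (length(bad))
      stop(sprintf("unknown %s key(s): %s", where, paste(bad, collapse = ", ")))
  }
  check_keys(raw, CONFIG_KEYS, "config")
  args <- raw[intersect(names(raw), c("targets", "stock", "budget_t_ref",
                                      "budget_p_ref", "vial", "replicates",
                                      "seed", "loaded_volume",
                                      "vial_capacity"))]
  if (!is.null(raw$constraints)) {
    check_keys(raw$constraints, CONSTRAINT_KEYS, "constraints")
    args$constraints <- do.call(instrument_constraints, raw$constraints)
  }
  if (!is.null(raw$geometry)) {
    check_keys(raw$geometry, GEOMETRY_KEYS, "geometry")
    args$geometry <- do.call(capillary_geometry, raw$geometry)
  }
  if (!is.null(raw$fluid)) {
    check_keys(raw$fluid, FLUID_KEYS, "fluid")
    args$fluid <- do.call(fluid, raw$fluid)
  }
  if (!is.null(raw$noise)) {
    check_keys(raw$noise, c("area_cv", "migration_drift_cv", "baseline_sd"),
               "noise")
    args$noise <- do.call(noise_model, raw$noise)
  }
  if (!is.null(raw$analytes)) {
    args$analytes <- lapply(raw$analytes, function(a) {
      check_keys(a, c("name", "migration_time", "response_factor",
                      "peak_width_sigma"), "analyte")
      do.call(analyte_model, a)
    })
    names(args$analytes) <- vapply(args$analytes, function(a) a$name,
                                   character(1))
  }
  do.call(ahmt_config, args)
}

#' @export
print.ahmt_config <- function(x, ...) {
  cat(sprintf("AHMT run config (%s vials): %d targets, stock %g ug/mL, budget %g psi min, %d replicates, seed %d\n",
              x$vial, length(x$targets), x$stock, x$budget, x$replicates,
              x$seed))
  invisible(x)
}
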