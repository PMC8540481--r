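# Composition of constituted calibration solutions.
#
# Each collection vial receives volumes of WS and DBGE; species
# concentrations in the constituted solution are volume-weighted averages.
# Because both source solutions carry the internal standard at the same
# level, the IS concentration is invariant across all calibration levels.

#' Define a solution
#'
#' @param name Label.
#' @param analytes Named numeric vector of analyte concentrations, ug/mL
#'   (may be empty for a pure diluent).
#' @param is_conc Internal-standard concentration, ug/mL.
#' @return An object of class `solution`.
#' @examples
#' working_standard()
#' diluent()
#' @export
solution <- function(name, analytes = numeric(0), is_conc = 0) {
  stopifnot(is.numeric(analytes), all(analytes >= 0),
            is.numeric(is_conc), is_conc >= 0)
  if (length(analytes) && is.null(names(analytes)))
    stop("analyte concentrations must be named")
  structure(list(name = as.character(name), analytes = analytes,
                 is_conc = is_conc),
            class = "solution")
}

#' @export
print.solution <- function(x, ...) {
  cat(sprintf("Solution '%s': IS %g ug/mL", x$name, x$is_conc))
  if (length(x$analytes))
    cat("; ", paste(sprintf("%s %g", names(x$analytes), x$analytes),
                    collapse = ", "), " ug/mL", sep = "")
  cat("\n")
  invisible(x)
}

#' Shipped source solutions
#'
#' `working_standard()` is the WS mixture: prilocaine and bupivacaine at
#' 100 ug/mL each plus the internal standard (procaine) at 100 ug/mL.
#' `diluent()` is the 10-fold water-diluted background electrolyte (DBGE)
#' spiked with the internal standard at 100 ug/mL, so the IS level is the
#' same in every constituted solution.
#'
#' @param conc Analyte concentration of the working standard, ug/mL.
#' @param is_conc Internal-standard concentration, ug/mL.
#' @return A [solution()].
#' @export
working_standard <- function(conc = 100, is_conc = 100) {
  solution("WS", c(prilocaine = conc, bupivacaine = conc), is_conc = is_conc)
}

#' @rdname working_standard
#' @export
diluent <- function(is_conc = 100) {
  solution("DBGE", is_conc = is_conc)
}

#' Mix solutions by volume
#'
#' Volume-weighted, mass-conservative mixing: the concentration of each
#' species in the mixture is sum(c_i v_i) / sum(v_i).
#'
#' @param components List of `list(solution = <solution>, volume = <uL>)`
#'   entries; at least one volume must be positive.
#' @param name Label for the mixture.
#' @return A [solution()] of the combined composition, with the total
#'   volume (uL) attached as attribute `volume`.
#' @examples
#' mix(list(list(solution = working_standard(), volume = 50),
#'          list(solution = diluent(), volume = 50)))
#' @export
mix <- function(components, name = "mixture") {
  stopifnot(is.list(components), length(components) >= 1)
  vols <- vapply(components, function(k) k$volume, numeric(1))
  stopifnot(all(vols >= 0))
  total <- sum(vols)
  if (total <= 0) stop("all component volumes are zero")
  species <- unique(unlist(lapply(components,
                                  function(k) names(k$solution$analytes))))
  # centered accumulation: averaging deviations from the first component's
  # value keeps the weighted mean exact when all components agree
  wmean <- function(conc) {
    conc[1] + sum((conc - conc[1]) * vols) / total
  }
  analytes <- vapply(species, function(s) {
    conc <- vapply(components, function(k) {
      c_s <- k$solution$analytes[s]
      if (is.na(c_s)) 0 else unname(c_s)
    }, numeric(1))
    wmean(conc)
  }, numeric(1))
  is_conc <- wmean(vapply(components, function(k) k$solution$is_conc,
                          numeric(1)))
  out <- solution(name, analytes, is_conc)
  attr(out, "volume") <- total
  out
}

#' Composition of a scheduled calibration solution
#'
#' Converts the schedule's two transfers to delivered volumes with the
#' laminar-flow model and mixes the sources. Because both volumes come
#' from the same flow model, geometry and viscosity cancel in the ratio:
#' the composition depends on the pressure-time products only.
#'
#' @param schedule A [plan_level()] schedule.
#' @param geometry A [capillary_geometry()].
#' @param fluid A [fluid()].
#' @param ws,dbge Source [solution()]s.
#' @return A [solution()]; for a pass-through (undiluted) schedule, the
#'   working solution itself.
#' @examples
#' s <- plan_level(6.25, 100, reference_budget(10, 2), nano_constraints())
#' schedule_to_composition(s, capillary_geometry(), fluid())
#' @export
schedule_to_composition <- function(schedule, geometry, fluid,
                                    ws = working_standard(),
                                    dbge = diluent()) {
  stopifnot(inherits(schedule, "dilution_schedule"))
  if (schedule$undiluted) {
    out <- ws
    out$name <- sprintf("level %g (undiluted WS)", schedule$target_concentration)
    return(out)
  }
  v_ws <- delivered_volume(schedule$ws_step, geometry, fluid)
  v_db <- delivered_volume(schedule$dbge_step, geometry, fluid)
  mix(list(list(solution = ws, volume = v_ws),
           list(solution = dbge, volume = v_db)),
      name = sprintf("level %g", schedule$target_concentration))
}
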