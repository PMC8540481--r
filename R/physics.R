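# Unit conversions and the laminar-flow model that turns (pressure, time)
# into delivered volume through the capillary.

#' psi / kPa conversion
#'
#' Beckman CE pressure systems are programmed in psi; publications usually
#' report kPa alongside. 1 psi = 6.894757 kPa.
#'
#' @param p Pressure in psi (`psi_to_kpa`) or kPa (`kpa_to_psi`). Vectorised.
#' @return Numeric vector of converted pressures.
#' @examples
#' psi_to_kpa(20)   # 137.8951, prints as 137.90 kPa
#' kpa_to_psi(psi_to_kpa(2.5))
#' @export
psi_to_kpa <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)))
  p * 6.894757
}

#' @rdname psi_to_kpa
#' @export
kpa_to_psi <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)))
  p / 6.894757
}

PSI_TO_PA <- 6894.757

#' Capillary geometry
#'
#' Fused-silica capillary dimensions. The total length drives dispensing
#' (pressure-driven flow traverses the whole capillary); the effective
#' length (inlet to detector window) is detector metadata only.
#'
#' @param total_length_cm Total capillary length in cm.
#' @param effective_length_cm Length to the detector window in cm; must be
#'   shorter than the total length.
#' @param id_um Inner diameter in micrometres.
#' @return An object of class `capillary_geometry` with lengths in metres.
#' @examples
#' capillary_geometry()  # the 30.5 / 20.5 cm, 50 um default
#' @export
capillary_geometry <- function(total_length_cm = 30.5,
                               effective_length_cm = 20.5,
                               id_um = 50) {
  stopifnot(is.numeric(total_length_cm), total_length_cm > 0,
            is.numeric(effective_length_cm), effective_length_cm > 0,
            is.numeric(id_um), id_um > 0)
  if (effective_length_cm >= total_length_cm)
    stop("effective length must be strictly shorter than total length")
  structure(list(total_length = total_length_cm / 100,
                 effective_length = effective_length_cm / 100,
                 inner_diameter = id_um * 1e-6),
            class = "capillary_geometry")
}

#' @export
print.capillary_geometry <- function(x, ...) {
  cat(sprintf("Capillary: %.1f cm total, %.1f cm to detector, ID %.0f um\n",
              x$total_length * 100, x$effective_length * 100,
              x$inner_diameter * 1e6))
  invisible(x)
}

#' Fluid properties
#'
#' @param viscosity_mpas Dynamic viscosity in mPa s (= cP). The default,
#'   0.89 mPa s, is water near 25 degC; the dilute aqueous working and
#'   diluent solutions are treated as having equal, water-like viscosity.
#' @param name Label used in printing and reagent budgets.
#' @return An object of class `fluid` with viscosity in Pa s.
#' @export
fluid <- function(viscosity_mpas = 0.89, name = "water") {
  stopifnot(is.numeric(viscosity_mpas), viscosity_mpas > 0)
  structure(list(viscosity = viscosity_mpas * 1e-3, name = as.character(name)),
            class = "fluid")
}

#' @export
print.fluid <- function(x, ...) {
  cat(sprintf("Fluid '%s': viscosity %.3g mPa s\n", x$name, x$viscosity * 1e3))
  invisible(x)
}

#' Hagen-Poiseuille volumetric flow through the capillary
#'
#' Laminar flow through a cylindrical capillary of radius r and length L
#' under a pressure difference dP: Q = dP * pi * r^4 / (8 * eta * L).
#' Flow is strictly linear in the applied pressure and in 1/viscosity.
#'
#' @param geometry A [capillary_geometry()].
#' @param fluid A [fluid()].
#' @param dp_psi Applied pressure difference in psi; must be positive.
#' @return Volumetric flow in m^3/s.
#' @examples
#' poiseuille_flow(capillary_geometry(), fluid(), 20)  # ~7.79e-11 m^3/s
#' @export
poiseuille_flow <- function(geometry, fluid, dp_psi) {
  stopifnot(inherits(geometry, "capillary_geometry"), inherits(fluid, "fluid"),
            is.numeric(dp_psi), all(dp_psi > 0))
  r <- geometry$inner_diameter / 2
  dp_psi * PSI_TO_PA * pi * r^4 / (8 * fluid$viscosity * geometry$total_length)
}

#' Volume delivered by a timed pressure transfer
#'
#' Flow times duration; volume depends on pressure and time only through
#' their product, which is why the scheduler can trade time against
#' pressure freely.
#'
#' @param step A [transfer_step()], or anything with `pressure` (psi) and
#'   `duration` (min) fields.
#' @param geometry A [capillary_geometry()].
#' @param fluid A [fluid()].
#' @return Delivered volume in microlitres.
#' @examples
#' delivered_volume(transfer_step("WS", 10, 20),
#'                  capillary_geometry(), fluid())  # ~46.8 uL
#' @export
delivered_volume <- function(step, geometry, fluid) {
  stopifnot(is.numeric(step$duration), step$duration > 0)
  q <- poiseuille_flow(geometry, fluid, step$pressure)   # m^3/s
  q * step$duration * 60 * 1e9                           # -> uL
}

#' Volume equivalent of a pressure-time product
#'
#' @param product Pressure-time product in psi min.
#' @inheritParams delivered_volume
#' @return Volume in microlitres.
#' @export
product_volume <- function(product, geometry, fluid) {
  stopifnot(is.numeric(product), all(product >= 0))
  out <- numeric(length(product))
  pos <- product > 0
  if (any(pos))
    out[pos] <- poiseuille_flow(geometry, fluid, product[pos]) * 60 * 1e9
  out
}
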