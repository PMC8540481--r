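# Time-pressure dilution scheduler.
#
# Each calibration level is made by transferring working solution (WS) and
# diluent (DBGE) into one collection vial. Keeping the sum of the two
# pressure-time products constant across levels keeps the collected volume
# constant (flow is linear in pressure), so the delivered concentration is
# set purely by the split of the budget:
#
#   t_WS * p_WS + t_DBGE * p_DBGE = const,
#   c = c_stock * P_WS / (P_WS + P_DBGE).

GRID_TOL <- 1e-9

on_grid <- function(x, quantum) {
  abs(x / quantum - round(x / quantum)) < GRID_TOL
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x, quantum) {
  sign(x) * floor(abs(x) / quantum + 0.5) * quantum
}

#' One hydrodynamic transfer step
#'
#' @param solution Which solution is moved: `"WS"` (working standard) or
#'   `"DBGE"` (diluted background electrolyte, the diluent).
#' @param duration Transfer time in minutes, > 0.
#' @param pressure Transfer pressure in psi, > 0.
#' @return An object of class `transfer_step` carrying the pressure-time
#'   `product` (psi min) that determines the delivered volume.
#' @export
transfer_step <- function(solution, duration, pressure) {
  solution <- match.arg(solution, c("WS", "DBGE"))
  stopifnot(is.numeric(duration), duration > 0,
            is.numeric(pressure), pressure > 0)
  structure(list(solution = solution, duration = duration, pressure = pressure,
                 product = duration * pressure),
            class = "transfer_step")
}

#' @export
print.transfer_step <- function(x, ...) {
  cat(sprintf("%-4s %g min at %g psi (%.2f kPa), product %g psi min\n",
              x$solution, x$duration, x$pressure, psi_to_kpa(x$pressure),
              x$product))
  invisible(x)
}

#' Instrument pressure/time constraints
#'
#' The pressure system delivers pressures on a quantized grid inside a
#' working range; transfer times are programmed on a time grid with a
#' default duration (the minimum giving repeatable delivery) and a cap
#' keeping each transfer within a reasonable run time.
#'
#' @param p_min,p_max Usable pressure range, psi.
#' @param p_quantum Pressure grid spacing, psi.
#' @param t_default Default transfer time, min. 10 min is the shortest
#'   transfer found to give repeatable concentrations (CV < 3%).
#' @param t_max Longest acceptable transfer, min.
#' @param t_quantum Time grid spacing, min.
#' @return An object of class `instrument_constraints`.
#' @seealso [pcr_constraints()], [nano_constraints()] for the two shipped
#'   profiles.
#' @export
instrument_constraints <- function(p_min, p_max, p_quantum,
                                   t_default = 10, t_max = 15, t_quantum = 1) {
  stopifnot(is.numeric(p_min), is.numeric(p_max), p_min > 0, p_min <= p_max,
            is.numeric(p_quantum), p_quantum > 0,
            is.numeric(t_quantum), t_quantum > 0,
            is.numeric(t_default), is.numeric(t_max), t_default > 0,
            t_default <= t_max)
  structure(list(p_min = p_min, p_max = p_max, p_quantum = p_quantum,
                 t_default = t_default, t_max = t_max, t_quantum = t_quantum),
            class = "instrument_constraints")
}

#' @export
print.instrument_constraints <- function(x, ...) {
  cat(sprintf(
    "Constraints: p in [%g, %g] psi (grid %g), t default %g / max %g min (grid %g)\n",
    x$p_min, x$p_max, x$p_quantum, x$t_default, x$t_max, x$t_quantum))
  invisible(x)
}

#' Shipped constraint profiles
#'
#' `pcr_constraints()` is the standard PCR-vial configuration: 2.5-30 psi
#' in 0.5 psi steps. `nano_constraints()` is the low-volume nanoVial
#' configuration: pressures from 0.5 psi in 0.1 psi steps up to 3.8 psi
#' (the largest pressure used for nanoVials, not an instrument limit).
#' Both use a 10 min default transfer, 15 min cap, integer minutes.
#'
#' @return An [instrument_constraints()] object.
#' @export
pcr_constraints <- function() {
  instrument_constraints(p_min = 2.5, p_max = 30, p_quantum = 0.5)
}

#' @rdname pcr_constraints
#' @export
nano_constraints <- function() {
  instrument_constraints(p_min = 0.5, p_max = 3.8, p_quantum = 0.1)
}

#' Pressure-time budget of a calibration series
#'
#' The budget is fixed by the mid (2-fold dilution) level, where WS and
#' DBGE are transferred with identical settings, so the total is twice
#' the reference product.
#'
#' @param t_ref Reference transfer time, min.
#' @param p_ref Reference pressure, psi.
#' @return Budget in psi min.
#' @examples
#' reference_budget(10, 20)  # PCR series: 400 psi min
#' reference_budget(10, 2)   # nanoVial series: 40 psi min
#' @export
reference_budget <- function(t_ref, p_ref) {
  stopifnot(is.numeric(t_ref), t_ref > 0, is.numeric(p_ref), p_ref > 0)
  2 * t_ref * p_ref
}

# Realize a pressure-time product as an on-grid (t, p) pair.
# Preference order: keep t at t_default and round p to the pressure grid;
# if the needed pressure exceeds p_max, stretch t minimally so that an
# exact on-grid pressure preserves the product; if it falls below p_min,
# pin p at p_min and stretch/shrink t on the time grid.
resolve_product <- function(P, constraints, what = "transfer") {
  cn <- constraints
  p0 <- P / cn$t_default
  if (p0 >= cn$p_min - GRID_TOL && p0 <= cn$p_max + GRID_TOL) {
    p <- round_half_away(p0, cn$p_quantum)
    p <- min(max(p, cn$p_min), cn$p_max)
    return(list(duration = cn$t_default, pressure = p))
  }
  if (p0 > cn$p_max) {
    t_grid <- seq(cn$t_default + cn$t_quantum, cn$t_max, by = cn$t_quantum)
    for (t in t_grid) {
      p <- P / t
      if (p <= cn$p_max + GRID_TOL && p >= cn$p_min - GRID_TOL &&
          on_grid(p, cn$p_quantum))
        return(list(duration = t, pressure = round(p / cn$p_quantum) * cn$p_quantum))
    }
    stop(sprintf(
      "scheduling infeasible for %s: product %g psi min needs p > %g psi at every grid time up to %g min",
      what, P, cn$p_max, cn$t_max))
  }
  # p0 < p_min: pin pressure, adjust time
  t <- round_half_away(P / cn$p_min, cn$t_quantum)
  if (t <= 0 || t > cn$t_max + GRID_TOL)
    stop(sprintf(
      "scheduling infeasible for %s: product %g psi min has no on-grid time at p_min %g psi",
      what, P, cn$p_min))
  list(duration = t, pressure = cn$p_min)
}

#' Plan one calibration level
#'
#' Splits the pressure-time budget between the WS and DBGE transfers in
#' proportion to the target dilution, then realizes each ideal product as
#' an on-grid (time, pressure) pair under the instrument constraints. The
#' achieved concentration is recomputed from the realized products, so any
#' grid-rounding error is reported, never hidden.
#'
#' @param c_target Target analyte concentration, ug/mL; must satisfy
#'   `0 < c_target <= c_stock`. `c_target == c_stock` yields a pass-through
#'   (undiluted) level with no transfers.
#' @param c_stock Working-solution analyte concentration, ug/mL.
#' @param budget Pressure-time budget, psi min; see [reference_budget()].
#' @param constraints An [instrument_constraints()] object.
#' @return An object of class `dilution_schedule`: fields
#'   `target_concentration`, `ws_step`, `dbge_step`, `budget`,
#'   `achieved_concentration`, `relative_dilution_error`, `undiluted`.
#' @examples
#' plan_level(6.25, 100, reference_budget(10, 20), pcr_constraints())
#' @export
plan_level <- function(c_target, c_stock, budget, constraints) {
  stopifnot(is.numeric(c_target), is.numeric(c_stock), is.numeric(budget),
            c_stock > 0, budget > 0,
            inherits(constraints, "instrument_constraints"))
  if (c_target <= 0 || c_target > c_stock)
    stop(sprintf("target %g ug/mL must lie in (0, stock = %g]", c_target, c_stock))

  if (abs(c_target - c_stock) < GRID_TOL * c_stock) {
    return(structure(list(target_concentration = c_target,
                          ws_step = NULL, dbge_step = NULL,
                          budget = budget,
                          achieved_concentration = c_stock,
                          relative_dilution_error = 0,
                          undiluted = TRUE),
                     class = "dilution_schedule"))
  }

  P_ws <- budget * c_target / c_stock
  P_dbge <- budget - P_ws
  ws <- resolve_product(P_ws, constraints,
                        sprintf("WS at level %g ug/mL", c_target))
  db <- resolve_product(P_dbge, constraints,
                        sprintf("DBGE at level %g ug/mL", c_target))
  ws_step <- transfer_step("WS", ws$duration, ws$pressure)
  dbge_step <- transfer_step("DBGE", db$duration, db$pressure)
  achieved <- c_stock * ws_step$product / (ws_step$product + dbge_step$product)
  structure(list(target_concentration = c_target,
                 ws_step = ws_step, dbge_step = dbge_step,
                 budget = budget,
                 achieved_concentration = achieved,
                 relative_dilution_error = (achieved - c_target) / c_target,
                 undiluted = FALSE),
            class = "dilution_schedule")
}

#' @export
print.dilution_schedule <- function(x, ...) {
  cat(sprintf("Level %g ug/mL (budget %g psi min)\n",
              x$target_concentration, x$budget))
  if (x$undiluted) {
    cat("  undiluted working solution (pass-through, no transfers)\n")
  } else {
    cat("  "); print(x$ws_step)
    cat("  "); print(x$dbge_step)
    cat(sprintf("  achieved %.4g ug/mL (relative dilution error %+.3g%%)\n",
                x$achieved_concentration, 100 * x$relative_dilution_error))
  }
  invisible(x)
}

#' Plan a calibration series
#'
#' One [plan_level()] schedule per target concentration.
#'
#' @param targets Vector of target concentrations, ug/mL.
#' @inheritParams plan_level
#' @return An object of class `ahmt_plan`: a list of `dilution_schedule`
#'   objects with the configuration attached. `as.data.frame()` gives the
#'   long schedule table (one row per transfer step).
#' @examples
#' plan <- plan_series(c(6.25, 12.5, 25, 37.5, 50, 75), 100,
#'                     reference_budget(10, 20), pcr_constraints())
#' as.data.frame(plan)
#' @export
plan_series <- function(targets, c_stock, budget, constraints) {
  stopifnot(length(targets) >= 1)
  schedules <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    schedules[[i]] <- tryCatch(
      plan_level(targets[i], c_stock, budget, constraints),
      error = function(e) stop(sprintf("level %d (%g ug/mL): %s",
                                       i, targets[i], conditionMessage(e)),
                               call. = FALSE))
  }
  structure(schedules, class = "ahmt_plan",
            c_stock = c_stock, budget = budget, constraints = constraints)
}

#' @export
as.data.frame.ahmt_plan <- function(x, ...) {
  rows <- lapply(x, function(s) {
    if (s$undiluted) {
      data.frame(level = s$target_concentration, solution = "WS",
                 t_min = NA_real_, p_psi = NA_real_, p_kpa = NA_real_,
                 product = NA_real_,
                 achieved_conc = s$achieved_concentration,
                 rel_error = 0, undiluted = TRUE)
    } else {
      data.frame(level = s$target_concentration,
                 solution = c("WS", "DBGE"),
                 t_min = c(s$ws_step$duration, s$dbge_step$duration),
                 p_psi = c(s$ws_step$pressure, s$dbge_step$pressure),
                 p_kpa = round(psi_to_kpa(c(s$ws_step$pressure,
                                            s$dbge_step$pressure)), 2),
                 product = c(s$ws_step$product, s$dbge_step$product),
                 achieved_conc = s$achieved_concentration,
                 rel_error = s$relative_dilution_error,
                 undiluted = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.ahmt_plan <- function(x, ...) {
  cat(sprintf("AHMT dilution plan: %d levels, stock %g ug/mL, budget %g psi min\n",
              length(x), attr(x, "c_stock"), attr(x, "budget")))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}
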