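# Timed method-sequence builder.
#
# Expands a dilution plan into the full ordered event list of one
# preparation run: capillary rinses, solution fills, the per-vial WS and
# DBGE transfers, tip cleaning, and per-vial air-bubbling mixing. The two
# flow modes, reverse (R) and forward (F), contain the same events and
# differ only in which tray holds the sources versus the collection vials.

#' Rinse / handling protocol
#'
#' Durations (min) of the fixed steps around the transfers. Defaults are
#' the published preparation protocol: water 1.5 / methanol 1.0 / air 1.5
#' before a 2 min WS fill; water 3.0 before a 2 min DBGE fill; water,
#' methanol and air 1.5 each afterwards; 1 min of 30 psi air bubbling per
#' vial to mix. Rinses and fills run at 20 psi. Tip cleaning (a dip into a
#' water vial between vials) has no published duration and defaults to 0.
#'
#' @param rinse_pressure Pressure for rinses and fills, psi.
#' @param pre_ws Named durations before the WS transfers (water, methanol,
#'   air, fill), min.
#' @param pre_dbge Named durations before the DBGE transfers (water, fill),
#'   min.
#' @param post Named durations after the DBGE transfers (water, methanol,
#'   air), min.
#' @param mix_duration,mix_pressure Per-vial air-bubbling mix, min and psi.
#' @param tip_clean_duration Per-vial tip dip, min.
#' @return A list of class `rinse_protocol`.
#' @export
rinse_protocol <- function(rinse_pressure = 20,
                           pre_ws = c(water = 1.5, methanol = 1.0,
                                      air = 1.5, fill = 2.0),
                           pre_dbge = c(water = 3.0, fill = 2.0),
                           post = c(water = 1.5, methanol = 1.5, air = 1.5),
                           mix_duration = 1, mix_pressure = 30,
                           tip_clean_duration = 0) {
  stopifnot(all(pre_ws >= 0), all(pre_dbge >= 0), all(post >= 0),
            mix_duration >= 0, tip_clean_duration >= 0, rinse_pressure > 0,
            mix_pressure > 0)
  structure(list(rinse_pressure = rinse_pressure, pre_ws = pre_ws,
                 pre_dbge = pre_dbge, post = post,
                 mix_duration = mix_duration, mix_pressure = mix_pressure,
                 tip_clean_duration = tip_clean_duration),
            class = "rinse_protocol")
}

#' Minimal protocol with no rinses or mixing
#'
#' Useful for isolating the transfer times themselves.
#' @return A [rinse_protocol()] with all fixed durations zero except a
#'   1 min mix.
#' @export
empty_protocol <- function() {
  rinse_protocol(pre_ws = c(water = 0, methanol = 0, air = 0, fill = 0),
                 pre_dbge = c(water = 0, fill = 0),
                 post = c(water = 0, methanol = 0, air = 0))
}

seq_event <- function(kind, liquid, duration, pressure = NA_real_,
                      source_tray = NA_character_, dest_tray = NA_character_,
                      vial = NA_character_, counted = TRUE) {
  data.frame(kind = kind, liquid = liquid, duration = duration,
             pressure = pressure, source_tray = source_tray,
             dest_tray = dest_tray, vial = vial, counted = counted)
}

#' Build the timed event sequence for a preparation run
#'
#' @param schedules An [plan_series()] plan or list of [plan_level()]
#'   schedules. Pass-through (undiluted) levels emit no transfer or mix
#'   events.
#' @param mode Flow direction: `"R"` (reverse; sources on the outlet tray,
#'   collection vials on the inlet tray) or `"F"` (forward; swapped).
#' @param protocol A [rinse_protocol()].
#' @param separation Optionally append annotation-only separation events
#'   (injection, voltage run) per vial; these are excluded from the
#'   preparation-time total.
#' @return An object of class `method_sequence`: fields `mode`, `events`
#'   (data frame), `total_duration` (min; counted preparation events only).
#' @examples
#' plan <- plan_series(c(6.25, 12.5, 25, 37.5, 50, 75), 100,
#'                     reference_budget(10, 20), pcr_constraints())
#' build_sequence(plan, mode = "R")
#' @export
build_sequence <- function(schedules, mode = c("R", "F"),
                           protocol = rinse_protocol(),
                           separation = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(protocol, "rinse_protocol"))
  if (inherits(schedules, "dilution_schedule")) schedules <- list(schedules)
  if (length(schedules) == 0) stop("no schedules to sequence")
  stopifnot(all(vapply(schedules, inherits, logical(1), "dilution_schedule")))

  src <- if (mode == "R") "outlet" else "inlet"
  dst <- if (mode == "R") "inlet" else "outlet"
  pp <- protocol
  active <- Filter(function(s) !s$undiluted, schedules)
  vial_of <- function(s) sprintf("cal_%g", s$target_concentration)

  ev <- list(
    seq_event("rinse", "water", pp$pre_ws[["water"]], pp$rinse_pressure, src, dst),
    seq_event("rinse", "methanol", pp$pre_ws[["methanol"]], pp$rinse_pressure, src, dst),
    seq_event("rinse", "air", pp$pre_ws[["air"]], pp$rinse_pressure, src, dst),
    seq_event("fill", "WS", pp$pre_ws[["fill"]], pp$rinse_pressure, src, dst))
  for (s in active) {
    ev <- c(ev, list(
      seq_event("tip_clean", "water", pp$tip_clean_duration),
      seq_event("transfer", "WS", s$ws_step$duration, s$ws_step$pressure,
                src, dst, vial_of(s))))
  }
  ev <- c(ev, list(
    seq_event("rinse", "water", pp$pre_dbge[["water"]], pp$rinse_pressure, src, dst),
    seq_event("fill", "DBGE", pp$pre_dbge[["fill"]], pp$rinse_pressure, src, dst)))
  for (s in active) {
    ev <- c(ev, list(
      seq_event("tip_clean", "water", pp$tip_clean_duration),
      seq_event("transfer", "DBGE", s$dbge_step$duration, s$dbge_step$pressure,
                src, dst, vial_of(s))))
  }
  ev <- c(ev, list(
    seq_event("rinse", "water", pp$post[["water"]], pp$rinse_pressure, src, dst),
    seq_event("rinse", "methanol", pp$post[["methanol"]], pp$rinse_pressure, src, dst),
    seq_event("rinse", "air", pp$post[["air"]], pp$rinse_pressure, src, dst)))
  for (s in active) {
    ev <- c(ev, list(
      seq_event("mix", "air", pp$mix_duration, pp$mix_pressure, src, dst,
                vial_of(s))))
  }
  if (isTRUE(separation)) {
    for (s in schedules) {
      ev <- c(ev, list(
        seq_event("separate", "sample", 6 / 60, 0.5, src, dst, vial_of(s),
                  counted = FALSE)))
    }
  }
  events <- do.call(rbind, ev)
  events <- events[events$duration > 0 | events$kind %in% c("tip_clean", "separate"), ]
  rownames(events) <- NULL
  structure(list(mode = mode, events = events,
                 total_duration = sum(events$duration[events$counted]),
                 schedules = schedules, protocol = protocol),
            class = "method_sequence")
}

#' @export
print.method_sequence <- function(x, ...) {
  cat(sprintf("AHMT method sequence, mode %s: %d events, %.1f min (%.2f h)\n",
              x$mode, nrow(x$events), x$total_duration, x$total_duration / 60))
  print(x$events[, c("kind", "liquid", "duration", "pressure", "vial")],
        digits = 3)
  invisible(x)
}

#' @export
as.data.frame.method_sequence <- function(x, ...) {
  cbind(index = seq_len(nrow(x$events)), x$events)
}

#' Reagent consumption of a sequence
#'
#' Sums the model-predicted delivered volume over every pressurized liquid
#' event (rinses, fills and transfers; air is excluded) and reports the
#' per-vial collected volume. Loaded source volumes let the caller check
#' that consumption stays within what was put on the tray.
#'
#' @param seq A [build_sequence()] result.
#' @param geometry A [capillary_geometry()].
#' @param fluid A [fluid()].
#' @param loaded_volume Volume loaded per source vial, uL.
#' @param vial_capacity Collection-vial capacity, uL; a warning is issued
#'   if any vial collects more.
#' @return List with `dispensed` (named uL per liquid), `per_vial`
#'   (named uL collected per vial), `loaded_volume`.
#' @export
reagent_budget <- function(seq, geometry, fluid,
                           loaded_volume = 200, vial_capacity = 200) {
  stopifnot(inherits(seq, "method_sequence"))
  ev <- seq$events
  liq <- ev[ev$liquid != "air" & ev$kind %in% c("rinse", "fill", "transfer") &
              ev$duration > 0, ]
  dispensed <- if (nrow(liq)) {
    vols <- mapply(function(d, p) {
      delivered_volume(list(duration = d, pressure = p), geometry, fluid)
    }, liq$duration, liq$pressure)
    tapply(vols, liq$liquid, sum)
  } else numeric(0)
  tr <- ev[ev$kind == "transfer" & ev$duration > 0, ]
  per_vial <- if (nrow(tr)) {
    vols <- mapply(function(d, p) {
      delivered_volume(list(duration = d, pressure = p), geometry, fluid)
    }, tr$duration, tr$pressure)
    tapply(vols, tr$vial, sum)
  } else numeric(0)
  if (length(per_vial) && any(per_vial > vial_capacity))
    warning(sprintf("collected volume exceeds vial capacity (%g uL) in: %s",
                    vial_capacity,
                    paste(names(per_vial)[per_vial > vial_capacity],
                          collapse = ", ")))
  list(dispensed = c(dispensed), per_vial = c(per_vial),
       loaded_volume = loaded_volume)
}
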