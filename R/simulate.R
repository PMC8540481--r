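# Synthetic electropherogram generator.
#
# Produces detector traces with known ground truth so the calibration and
# comparison statistics can be exercised end to end without instrument
# data. Each analyte contributes a Gaussian peak whose true area scales
# with concentration times migration time -- slower analytes reside longer
# in the detector window, which is exactly the velocity dependence that
# time-corrected peak areas (TCPA) remove. Migration-time drift is drawn
# once per run and shared by all peaks of that run, so the analyte/IS
# TCPA ratio cancels it.

#' Analyte peak model
#'
#' @param name Analyte label.
#' @param migration_time Nominal migration time, min.
#' @param response_factor Detector response, area units per (ug/mL x min):
#'   true area = response_factor x concentration x migration time.
#' @param peak_width_sigma Gaussian peak standard deviation, min.
#' @return An object of class `analyte_model`.
#' @export
analyte_model <- function(name, migration_time, response_factor = 1,
                          peak_width_sigma = 0.02) {
  stopifnot(migration_time > 0, response_factor > 0, peak_width_sigma > 0)
  structure(list(name = as.character(name), migration_time = migration_time,
                 response_factor = response_factor,
                 peak_width_sigma = peak_width_sigma),
            class = "analyte_model")
}

#' Default analyte panel
#'
#' Procaine (the internal standard), prilocaine and bupivacaine at
#' migration times 1.6, 2.1 and 2.6 min. The times and response factors
#' are fixture choices giving baseline-resolved peaks on a short
#' capillary; they are not measured values.
#'
#' @return A named list of [analyte_model()] objects.
#' @export
default_analytes <- function() {
  list(procaine = analyte_model("procaine", 1.6, response_factor = 1.2),
       prilocaine = analyte_model("prilocaine", 2.1, response_factor = 1.0),
       bupivacaine = analyte_model("bupivacaine", 2.6, response_factor = 0.55))
}

#' Noise model for synthetic runs
#'
#' @param area_cv Coefficient of variation of the multiplicative
#'   (log-normal) peak-area noise. The default 2% sits under the
#'   repeatability acceptance level of the preparation protocol (CV < 3%).
#' @param migration_drift_cv CV of the per-run common migration-time
#'   drift.
#' @param baseline_sd Additive Gaussian baseline noise, AU.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(area_cv = 0.02, migration_drift_cv = 0.005,
                        baseline_sd = 0) {
  stopifnot(area_cv >= 0, migration_drift_cv >= 0, baseline_sd >= 0)
  structure(list(area_cv = area_cv, migration_drift_cv = migration_drift_cv,
                 baseline_sd = baseline_sd),
            class = "noise_model")
}

concentration_of <- function(composition, analyte) {
  if (analyte == "procaine") return(composition$is_conc)
  c_a <- composition$analytes[analyte]
  if (is.na(c_a)) 0 else unname(c_a)
}

#' Simulate one electropherogram
#'
#' @param composition A [solution()] giving the true concentrations
#'   (the internal standard procaine is read from `is_conc`).
#' @param analytes List of [analyte_model()]s.
#' @param noise A [noise_model()].
#' @param t_max Trace length, min.
#' @param rate Sampling rate, Hz.
#' @param seed Optional integer seed for this run.
#' @return An `electropherogram`: a data frame with columns `time` (min)
#'   and `absorbance` (AU), with the true peak table (analyte, true
#'   migration time, true area, concentration) in attribute `truth`.
#' @examples
#' tr <- simulate_run(working_standard(), default_analytes(),
#'                    noise_model(), seed = 1)
#' head(tr)
#' @export
simulate_run <- function(composition, analytes, noise = noise_model(),
                         t_max = 4, rate = 10, seed = NULL) {
  stopifnot(inherits(composition, "solution"), length(analytes) >= 1,
            inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  time <- seq(0, t_max, by = 1 / (rate * 60))
  absorb <- numeric(length(time))
  drift <- if (noise$migration_drift_cv > 0)
    stats::rnorm(1, 0, noise$migration_drift_cv) else 0
  truth <- data.frame(analyte = character(0), migration_time = numeric(0),
                      area = numeric(0), concentration = numeric(0))
  for (a in analytes) {
    conc <- concentration_of(composition, a$name)
    tm <- a$migration_time * (1 + drift)
    area <- a$response_factor * conc * tm
    if (noise$area_cv > 0 && area > 0) {
      sdlog <- sqrt(log(1 + noise$area_cv^2))
      area <- area * stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    if (area > 0)
      absorb <- absorb + area * stats::dnorm(time, tm, a$peak_width_sigma)
    truth <- rbind(truth, data.frame(analyte = a$name, migration_time = tm,
                                     area = area, concentration = conc))
  }
  if (noise$baseline_sd > 0)
    absorb <- absorb + stats::rnorm(length(time), 0, noise$baseline_sd)
  out <- data.frame(time = time, absorbance = absorb)
  attr(out, "truth") <- truth
  attr(out, "drift") <- drift
  class(out) <- c("electropherogram", "data.frame")
  out
}

#' Simulate a whole calibration series
#'
#' Replicate runs per calibration level with independent noise draws,
#' reproducible from a single seed.
#'
#' @param schedules A [plan_series()] plan (or list of schedules); the
#'   composition of each level comes from [schedule_to_composition()].
#' @param analytes List of [analyte_model()]s.
#' @param noise A [noise_model()].
#' @param replicates Runs per level (the standard protocol is triplicate).
#' @param seed Integer seed for the whole series.
#' @param geometry,fluid Physics configuration for the compositions.
#' @param ws,dbge Source solutions.
#' @param ... Passed to [simulate_run()] (`t_max`, `rate`).
#' @return A list of class `ahmt_series` of electropherograms; each
#'   element carries attributes `level` (achieved concentration scale
#'   factor on the WS analytes) and `replicate`.
#' @export
simulate_series <- function(schedules, analytes = default_analytes(),
                            noise = noise_model(), replicates = 3,
                            seed = NULL,
                            geometry = capillary_geometry(),
                            fluid = ahmt::fluid(),
                            ws = working_standard(), dbge = diluent(), ...) {
  stopifnot(replicates >= 1)
  if (inherits(schedules, "dilution_schedule")) schedules <- list(schedules)
  if (!is.null(seed)) set.seed(seed)
  runs <- list()
  for (i in seq_along(schedules)) {
    comp <- schedule_to_composition(schedules[[i]], geometry, fluid, ws, dbge)
    for (r in seq_len(replicates)) {
      tr <- simulate_run(comp, analytes, noise, ...)
      attr(tr, "level") <- schedules[[i]]$target_concentration
      attr(tr, "achieved") <- if (schedules[[i]]$undiluted)
        attr(tr, "truth") else NULL
      attr(tr, "composition") <- comp
      attr(tr, "replicate") <- r
      runs[[length(runs) + 1]] <- tr
    }
  }
  structure(runs, class = "ahmt_series",
            replicates = replicates, analytes = analytes)
}

#' @export
print.ahmt_series <- function(x, ...) {
  lev <- vapply(x, function(tr) attr(tr, "level"), numeric(1))
  cat(sprintf("Synthetic calibration series: %d runs over %d levels (%s ug/mL)\n",
              length(x), length(unique(lev)),
              paste(sort(unique(lev)), collapse = ", ")))
  invisible(x)
}

#' Write / read a trace as two-column CSV
#'
#' @param trace An electropherogram.
#' @param path File path.
#' @return `read_trace` returns an `electropherogram` data frame (without
#'   truth metadata, which is not persisted).
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_min = trace$time, AU = trace$absorbance),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path)
  out <- data.frame(time = d[[1]], absorbance = d[[2]])
  class(out) <- c("electropherogram", "data.frame")
  out
}

#' @export
plot.electropherogram <- function(x, ...) {
  plot(x$time, x$absorbance, type = "l", xlab = "time (min)",
       ylab = "absorbance (AU)", ...)
  invisible(x)
}
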