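# Signal processing and calibration statistics.
#
# Pipeline: integrate peaks -> time-corrected peak area (TCPA = area /
# migration time) -> analytical signal y = TCPA_analyte / TCPA_IS ->
# single-pass outlier screen on standardized residuals of an unweighted
# replicate-level fit -> average surviving replicates per level -> 1/x
# weighted least-squares calibration line -> back-calculation.

#' Integrate peaks from a trace
#'
#' Locates each analyte's apex inside a window around its nominal
#' migration time, subtracts a baseline estimated from the window edges,
#' and integrates by the trapezoidal rule.
#'
#' @param trace An electropherogram (columns `time`, `absorbance`).
#' @param analytes List of [analyte_model()]s defining the windows.
#' @param window Half-width of the integration window, min.
#' @param min_height Minimum apex height above baseline, AU; below this
#'   the peak is reported missing.
#' @return Data frame of class `peak_table` with columns `analyte`,
#'   `migration_time`, `area`, `tcpa`.
#' @export
integrate_peaks <- function(trace, analytes, window = 0.2,
                            min_height = 1e-4) {
  stopifnot(is.data.frame(trace), all(c("time", "absorbance") %in% names(trace)),
            length(analytes) >= 1)
  out <- lapply(analytes, function(a) {
    lo <- a$migration_time - window
    hi <- a$migration_time + window
    if (lo < min(trace$time) || hi > max(trace$time))
      stop(sprintf("window for %s [%.2f, %.2f] min outside trace range",
                   a$name, lo, hi))
    sel <- trace$time >= lo & trace$time <= hi
    tt <- trace$time[sel]
    yy <- trace$absorbance[sel]
    edge <- max(3L, ceiling(length(yy) * 0.05))
    baseline <- stats::median(c(utils::head(yy, edge), utils::tail(yy, edge)))
    apex <- which.max(yy)
    if (yy[apex] - baseline < min_height)
      stop(sprintf("no peak found for %s in [%.2f, %.2f] min",
                   a$name, lo, hi))
    y0 <- yy - baseline
    area <- sum(diff(tt) * (utils::head(y0, -1) + utils::tail(y0, -1)) / 2)
    tm <- tt[apex]
    data.frame(analyte = a$name, migration_time = tm, area = area,
               tcpa = area / tm)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Internal-standard signal ratios
#'
#' The analytical signal of each analyte is the ratio of time-corrected
#' peak areas, y = TCPA_analyte / TCPA_IS. The ratio is invariant under a
#' uniform migration-velocity change, because both TCPAs scale the same
#' way.
#'
#' @param peaks A [integrate_peaks()] table.
#' @param is_label Internal-standard analyte name.
#' @return Named numeric vector of signals, one per non-IS analyte.
#' @export
tcpa_signal <- function(peaks, is_label = "procaine") {
  stopifnot(is.data.frame(peaks))
  i <- match(is_label, peaks$analyte)
  if (is.na(i))
    stop(sprintf("internal standard '%s' not found among integrated peaks",
                 is_label))
  tcpa_is <- peaks$tcpa[i]
  rest <- peaks[-i, , drop = FALSE]
  stats::setNames(rest$tcpa / tcpa_is, rest$analyte)
}

#' Flag outlying replicate points by standardized residuals
#'
#' Fits an unweighted line to all replicate-level points and flags those
#' whose residual exceeds `threshold` residual standard deviations
#' (single pass, no re-rejection).
#'
#' @param x,y Replicate-level concentrations and signals.
#' @param threshold Standardized-residual cut-off.
#' @return Logical vector, `TRUE` = outlier.
#' @export
reject_outliers <- function(x, y, threshold = 2) {
  stopifnot(length(x) == length(y), length(x) >= 3, threshold > 0)
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  s <- sqrt(sum(res^2) / (length(x) - 2))
  if (s < .Machine$double.eps) return(rep(FALSE, length(x)))
  flags <- abs(res / s) > threshold
  if (all(flags))
    stop("degenerate calibration: every replicate point flagged as outlier")
  flags
}

weighted_line <- function(x, y, w) {
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  a <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  b <- yb - a * xb
  fitted <- a * x + b
  r2 <- 1 - sum(w * (y - fitted)^2) / sum(w * (y - yb)^2)
  list(a = a, b = b, r2 = r2)
}

#' Fit a weighted calibration line
#'
#' Weighted least squares of the averaged signal on concentration with
#' weights w = 1/x (the standard bioanalytical scheme: it equalizes the
#' relative influence of low and high calibrators under proportional
#' noise). Replicate screening, if requested, precedes averaging;
#' averaging precedes weighting.
#'
#' @param x Replicate-level concentrations, ug/mL; all > 0 (the weights
#'   must be defined).
#' @param y Replicate-level signals (TCPA ratios).
#' @param weights Weight function of x; default `function(x) 1/x`.
#' @param screen Apply [reject_outliers()] before averaging?
#' @param threshold Outlier cut-off passed to [reject_outliers()].
#' @return An object of class `calibration_fit` with coefficients
#'   `a` (slope, mL/ug) and `b` (intercept), the weighted `r2`, counts
#'   `n_used` / `n_rejected`, and the level-averaged data.
#' @examples
#' x <- rep(c(6.25, 12.5, 25, 50), each = 3)
#' y <- 0.02 * x - 0.01
#' calibration(x, y)
#' @export
calibration <- function(x, y, weights = function(x) 1 / x,
                        screen = TRUE, threshold = 2) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (any(x <= 0))
    stop("all concentrations must be positive: weights 1/x are undefined at 0")
  if (length(unique(x)) < 3)
    stop("need at least 3 distinct concentration levels")
  flagged <- if (screen && length(x) >= 3)
    reject_outliers(x, y, threshold) else rep(FALSE, length(x))
  xk <- x[!flagged]; yk <- y[!flagged]
  if (length(unique(xk)) < 3)
    stop("fewer than 3 distinct levels survive outlier screening")
  xm <- sort(unique(xk))
  ym <- vapply(xm, function(v) mean(yk[xk == v]), numeric(1))
  w <- weights(xm)
  if (any(!is.finite(w) | w <= 0)) stop("weights must be positive and finite")
  ls <- weighted_line(xm, ym, w)
  structure(list(a = ls$a, b = ls$b, r2 = ls$r2,
                 weights = weights,
                 n_used = sum(!flagged), n_rejected = sum(flagged),
                 outlier = flagged,
                 data = data.frame(x = xm, y = ym, w = w),
                 replicate_data = data.frame(x = x, y = y, outlier = flagged)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Weighted calibration (w = 1/x): y = %.*g x %+.*g, r2 = %.4f\n",
              digits, x$a, digits, x$b, x$r2))
  cat(sprintf("  %d replicate points used, %d rejected, %d levels\n",
              x$n_used, x$n_rejected, nrow(x$data)))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' @export
predict.calibration_fit <- function(object, newdata, ...) {
  x <- if (missing(newdata)) object$data$x else newdata
  object$a * x + object$b
}

#' @export
residuals.calibration_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' @export
summary.calibration_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- predict(object)
  d$x_back <- back_calculate(object, d$y)
  d$rel_error_pct <- 100 * (d$x_back - d$x) / d$x
  out <- list(fit = object, table = d)
  class(out) <- "summary.calibration_fit"
  out
}

#' @export
print.summary.calibration_fit <- function(x, ...) {
  print(x$fit)
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
plot.calibration_fit <- function(x, ...) {
  d <- x$replicate_data
  plot(d$x, d$y, pch = ifelse(d$outlier, 4, 1),
       xlab = "concentration (ug/mL)", ylab = "TCPA ratio", ...)
  graphics::abline(x$b, x$a)
  invisible(x)
}

#' Back-calculate concentrations from a fit
#'
#' @param fit A [calibration()] fit.
#' @param y Observed signals.
#' @return Estimated concentrations, x-hat = (y - b) / a.
#' @export
back_calculate <- function(fit, y) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (abs(fit$a) < .Machine$double.eps) stop("zero slope: cannot invert fit")
  (y - fit$b) / fit$a
}

#' Relative back-calculation error
#'
#' @param fit A [calibration()] fit.
#' @param x_true True concentrations.
#' @param y Observed signals.
#' @return Fractional errors (x_hat - x_true) / x_true.
#' @export
relative_error <- function(fit, x_true, y) {
  stopifnot(all(x_true > 0))
  (back_calculate(fit, y) - x_true) / x_true
}

#' Calibrate a simulated (or measured) series end to end
#'
#' Integrates every run, forms TCPA ratios against the internal standard,
#' and fits one weighted calibration per analyte.
#'
#' @param series An [simulate_series()] list of traces (each carrying a
#'   `composition` attribute), or a data frame with columns `analyte`,
#'   `x`, `y` of replicate-level points.
#' @param analytes List of [analyte_model()]s (needed for integration).
#' @param is_label Internal-standard name.
#' @param ... Passed to [calibration()].
#' @return Named list of `calibration_fit` objects (one per analyte),
#'   of class `calibration_set`, with the replicate-level signal table in
#'   attribute `signals`.
#' @export
calibrate_series <- function(series, analytes = default_analytes(),
                             is_label = "procaine", ...) {
  if (is.data.frame(series)) {
    pts <- series
  } else {
    rows <- lapply(series, function(tr) {
      comp <- attr(tr, "composition")
      peaks <- integrate_peaks(tr, analytes)
      y <- tcpa_signal(peaks, is_label)
      data.frame(analyte = names(y),
                 x = vapply(names(y), function(a) concentration_of(comp, a),
                            numeric(1)),
                 y = unname(y),
                 level = attr(tr, "level") %||% NA_real_,
                 replicate = attr(tr, "replicate") %||% NA_integer_)
    })
    pts <- do.call(rbind, rows)
  }
  fits <- lapply(split(pts, pts$analyte), function(d) {
    calibration(d$x, d$y, ...)
  })
  structure(fits, class = "calibration_set", signals = pts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.calibration_set <- function(x, ...) {
  for (nm in names(x)) {
    cat(nm, ": ", sep = "")
    print(x[[nm]])
  }
  invisible(x)
}
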