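# Deming errors-in-variables regression for method comparison.
#
# Ordinary least squares assumes the x variable is error-free; when both
# axes are back-calculated concentrations, both carry measurement error
# and OLS attenuates the slope. Deming regression minimizes
#   sum_i [ (y_i - yhat_i)^2 + delta * (x_i - xhat_i)^2 ]
# over points (xhat_i, yhat_i) on the line, where
#   delta = var(error in y) / var(error in x).
# The convention here puts the automatic mode on y and the manual
# reference on x.

#' Error-variance ratio for Deming regression
#'
#' @param sd_x,sd_y Standard deviations of the measurement errors in x
#'   and y (e.g. the mean replicate SDs of each mode).
#' @return delta = sd_y^2 / sd_x^2.
#' @export
deming_lambda <- function(sd_x, sd_y) {
  stopifnot(is.numeric(sd_x), is.numeric(sd_y))
  if (sd_x <= 0 || sd_y <= 0) stop("standard deviations must be positive")
  sd_y^2 / sd_x^2
}

deming_coef <- function(x, y, delta) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  s_xx <- sum((x - xb)^2) / (n - 1)
  s_yy <- sum((y - yb)^2) / (n - 1)
  s_xy <- sum((x - xb) * (y - yb)) / (n - 1)
  if (abs(s_xy) < .Machine$double.eps) {
    if (abs(s_yy - delta * s_xx) < .Machine$double.eps)
      return(c(a = 1, b = yb - xb))   # isotropic cloud: slope conventionally 1
    stop("orientation ambiguous: zero covariance with unequal scaled variances")
  }
  a <- ((s_yy - delta * s_xx) +
          sqrt((s_yy - delta * s_xx)^2 + 4 * delta * s_xy^2)) / (2 * s_xy)
  c(a = a, b = yb - a * xb)
}

#' Deming regression
#'
#' Closed-form errors-in-variables fit with error-variance ratio
#' `delta` = var_y / var_x. Standard errors of slope and intercept are
#' leave-one-out jackknife estimates.
#'
#' @param x Reference (e.g. manual-mode) concentrations.
#' @param y Test (e.g. automatic-mode) concentrations.
#' @param delta Error-variance ratio, y-to-x; see [deming_lambda()].
#' @return An object of class `deming_fit` with fields `a` (slope),
#'   `b` (intercept), `sa`, `sb` (jackknife SEs), `delta`, `n`.
#' @examples
#' x <- c(6.2, 12.4, 25.3, 37.0, 50.8, 74.2)
#' deming(x, 1.01 * x + 0.2, delta = 1)
#' @export
deming <- function(x, y, delta = 1) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            is.numeric(delta), delta > 0)
  if (length(x) < 3) stop("Deming regression needs at least 3 points")
  if (stats::var(x) == 0) stop("x values are all equal")
  cf <- deming_coef(x, y, delta)
  n <- length(x)
  loo <- vapply(seq_len(n), function(i) deming_coef(x[-i], y[-i], delta),
                numeric(2))
  sa <- sqrt((n - 1) / n * sum((loo[1, ] - mean(loo[1, ]))^2))
  sb <- sqrt((n - 1) / n * sum((loo[2, ] - mean(loo[2, ]))^2))
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 sa = sa, sb = sb, delta = delta, n = n,
                 data = data.frame(x = x, y = y)),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Deming regression (delta = %.4g, n = %d)\n", x$delta, x$n))
  cat(sprintf("  slope     a = %.*g  (SE %.3g)\n", digits, x$a, x$sa))
  cat(sprintf("  intercept b = %.*g  (SE %.3g)\n", digits, x$b, x$sb))
  invisible(x)
}

#' @export
coef.deming_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.deming_fit <- function(object, newdata, ...) {
  x <- if (missing(newdata)) object$data$x else newdata
  object$a * x + object$b
}

#' @export
plot.deming_fit <- function(x, ...) {
  plot(x$data$x, x$data$y, xlab = "reference concentration (ug/mL)",
       ylab = "test concentration (ug/mL)", ...)
  graphics::abline(x$b, x$a)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Compare automatic and manual calibration modes
#'
#' Deming regression of the automatic mode's back-calculated
#' concentrations (y) on the manual mode's (x). Perfect agreement is
#' slope 1, intercept 0.
#'
#' @param conc_auto,conc_manual Aligned per-level concentrations, ug/mL.
#' @param delta Error-variance ratio; either a number or `"auto"` to
#'   estimate it from per-level replicate SDs supplied via `sd_auto` /
#'   `sd_manual`.
#' @param sd_auto,sd_manual Optional per-level replicate SDs of each
#'   mode, used when `delta = "auto"` (delta = mean(sd_auto)^2 /
#'   mean(sd_manual)^2).
#' @return A [deming()] fit.
#' @export
compare_modes <- function(conc_auto, conc_manual, delta = 1,
                          sd_auto = NULL, sd_manual = NULL) {
  if (length(conc_auto) != length(conc_manual))
    stop("automatic and manual concentration vectors differ in length")
  if (identical(delta, "auto")) {
    if (is.null(sd_auto) || is.null(sd_manual))
      stop("delta = 'auto' needs sd_auto and sd_manual")
    delta <- deming_lambda(mean(sd_manual), mean(sd_auto))
  }
  deming(x = conc_manual, y = conc_auto, delta = delta)
}
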