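# Predicted-vs-measured comparison and tolerance-window derivation
# (MAE + k * SD of signed error) for CCS and Rt.

#' Linear calibration of predicted against measured values
#'
#' Ordinary least squares of \code{predicted} on \code{measured};
#' \code{r2} is the coefficient of determination of that fit.
#'
#' @param predicted,measured Equal-length numeric vectors, n >= 3.
#' @return List with \code{slope}, \code{intercept}, \code{r2}.
#' @export
fit_linear_calibration <- function(predicted, measured) {
  stopifnot(length(predicted) == length(measured))
  if (length(measured) < 3L) stop("insufficient-data error: need n >= 3")
  if (stats::sd(measured) == 0) {
    stop("degenerate-regression error: measured vector is constant")
  }
  fit <- stats::lm(predicted ~ measured)
  # a perfect fit (predicted == measured) is a legitimate input here
  s <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = s$r.squared)
}

#' Prediction-error statistics
#'
#' \code{mae} is the mean absolute error, \code{sd_error} the sample
#' standard deviation (n - 1 denominator) of the signed errors
#' (predicted - measured), and \code{sd_error_relative} expresses
#' \code{sd_error} as a percentage of the mean measured value.
#'
#' @param predicted,measured Equal-length numeric vectors, n >= 2.
#' @return List with \code{mae}, \code{sd_error}, \code{sd_error_relative}
#'   (percent), \code{n}.
#' @export
error_stats <- function(predicted, measured) {
  stopifnot(length(predicted) == length(measured))
  if (length(measured) < 2L) stop("insufficient-data error: need n >= 2")
  err <- predicted - measured
  mae <- mean(abs(err))
  sd_error <- stats::sd(err)
  list(mae = mae, sd_error = sd_error,
       sd_error_relative = 100 * sd_error / mean(measured),
       n = length(measured))
}

#' Derive a match-tolerance window from error statistics
#'
#' The tolerance used for annotation filtering is the mean absolute error
#' plus \code{k} standard deviations of the signed error (default k = 2).
#' With the CCS validation statistics MAE = 3.94 Å² and SD = 6.11 Å² this
#' yields 16.16 Å²; with the Rt cross-validation statistics 0.81 min and
#' 0.15 min it yields 1.11 min.
#'
#' @param mae Mean absolute error (>= 0), property units.
#' @param sd_error Standard deviation of the signed error (>= 0), property
#'   units.
#' @param k SD multiplier (> 0).
#' @return Tolerance in property units.
#' @examples
#' derive_tolerance(3.94, 6.11)  # 16.16
#' @export
derive_tolerance <- function(mae, sd_error, k = 2) {
  if (any(mae < 0) || any(sd_error < 0) || any(k <= 0)) {
    stop("domain error: mae, sd_error must be >= 0 and k > 0")
  }
  mae + k * sd_error
}

#' Relative error band
#'
#' k standard deviations expressed in percent, for drawing relative bands
#' around a calibration fit.
#'
#' @param sd_error_relative Relative SD in percent (>= 0).
#' @param k SD multiplier.
#' @return Band half-width in percent.
#' @export
relative_band <- function(sd_error_relative, k = 2) {
  if (any(sd_error_relative < 0)) stop("domain error: input must be >= 0")
  k * sd_error_relative
}

#' Full calibration of one predicted property
#'
#' Combines the linear fit, the error statistics, and the derived tolerance
#' window into one calibration record.
#'
#' @param predicted,measured Paired vectors (n >= 3).
#' @param property \code{"ccs"} or \code{"rt"} (annotation only).
#' @param k SD multiplier for the tolerance.
#' @return An object of class \code{calibration_result}: \code{property},
#'   \code{slope}, \code{intercept}, \code{r2}, \code{mae},
#'   \code{sd_error}, \code{sd_error_relative}, \code{tolerance}, \code{n}.
#' @export
calibrate_property <- function(predicted, measured,
                               property = c("ccs", "rt"), k = 2) {
  property <- match.arg(property)
  lin <- fit_linear_calibration(predicted, measured)
  es <- error_stats(predicted, measured)
  structure(c(list(property = property), lin, es,
              list(tolerance = derive_tolerance(es$mae, es$sd_error, k),
                   k = k)),
            class = "calibration_result")
}

#' Rt tolerance from cross-validation metrics
#'
#' For retention time the tolerance inputs are the cross-validation mean
#' MAE and the SD of the per-fold MAE (the per-compound residual variant is
#' available through \code{\link{calibrate_property}}).
#'
#' @param cv_metrics List with \code{mean_mae} and \code{sd_mae} as
#'   returned by \code{\link{cross_validate_rt}}.
#' @param k SD multiplier.
#' @return Tolerance in minutes.
#' @export
rt_tolerance_from_cv <- function(cv_metrics, k = 2) {
  derive_tolerance(cv_metrics$mean_mae, cv_metrics$sd_mae, k)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration (%s): predicted = %.3f x measured + %.3f, R2 = %.3f\n",
              x$property, x$slope, x$intercept, x$r2))
  cat(sprintf("  MAE = %.3f, SD = %.3f (%.2f%%), n = %d\n",
              x$mae, x$sd_error, x$sd_error_relative, x$n))
  cat(sprintf("  tolerance (MAE + %g SD) = %.3f\n", x$k, x$tolerance))
  invisible(x)
}
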