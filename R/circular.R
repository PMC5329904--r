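#' Wrap times onto a periodic range
#'
#' Reduces times modulo the period so that values below zero or beyond the
#' period "wrap around" onto `[0, period_units)`. All internal computation in
#' this package represents time as a fraction of the period on `[0, 1)`; hours
#' appear only at input/output boundaries.
#'
#' @param t Numeric vector of times (any real values).
#' @param period_units Length of the period in the same units as `t`
#'   (default 1, the scaled circle).
#' @return Numeric vector with `result %% period_units == result` and all
#'   values in `[0, period_units)`.
#' @examples
#' wrap_time(1.25)        # 0.25
#' wrap_time(-0.1)        # 0.9
#' wrap_time(25, 24)      # 1
#' @export
wrap_time <- function(t, period_units = 1) {
  check_finite(t, "t")
  if (!is.numeric(period_units) || length(period_units) != 1L ||
      !is.finite(period_units) || period_units <= 0)
    stop_ct("period_units must be a single positive number")
  r <- t %% period_units
  # floating-point mod of a tiny negative can land exactly on the period
  r[r >= period_units] <- 0
  r
}

#' Circular prediction error
#'
#' Minimal circular displacement between predicted and observed times on a
#' periodic scale, reported in hours. The signed error is the shorter arc from
#' observed to predicted, in `(-period/2, period/2]`; an exact half-period tie
#' is reported as `+period/2`.
#'
#' @param predicted,observed Numeric vectors of times scaled to `[0, 1)`.
#' @param period Period length in hours (default 24).
#' @return A data frame with columns `signed_error` and `absolute_error`
#'   (hours); `absolute_error <= period/2`.
#' @examples
#' circular_error(23 / 24, 1 / 24)  # signed -2 h, absolute 2 h
#' @export
circular_error <- function(predicted, observed, period = 24) {
  check_finite(predicted, "predicted")
  check_finite(observed, "observed")
  if (any(predicted < 0 | predicted >= 1) || any(observed < 0 | observed >= 1))
    stop_ct("times must be scaled to [0, 1)")
  d <- wrap_time(predicted - observed)
  signed <- ifelse(d > 0.5, d - 1, d) * period
  data.frame(signed_error = signed, absolute_error = abs(signed))
}

#' Circular mean of times on the unit circle
#'
#' Mean direction of a set of times scaled to `[0, 1)`:
#' `(1/2pi) * atan2(sum(sin(2 pi t)), sum(cos(2 pi t)))`, wrapped to `[0, 1)`.
#' Used to combine the predictions of several predictors into an ensemble.
#'
#' @param times Numeric vector of times in `[0, 1)`.
#' @param tol Degeneracy threshold on the mean resultant length; a nearly
#'   antipodal set (resultant length below `tol`) has no meaningful mean and
#'   raises an error rather than returning an arbitrary direction.
#' @return A single time in `[0, 1)`.
#' @examples
#' circular_mean(c(23 / 24, 1 / 24))  # 0, symmetric about midnight
#' @export
circular_mean <- function(times, tol = 1e-9) {
  check_finite(times, "times")
  if (length(times) == 0L) stop_ct("times must be non-empty")
  s <- sum(sin(2 * pi * times))
  cc <- sum(cos(2 * pi * times))
  if (sqrt(s^2 + cc^2) / length(times) <= tol)
    stop_ct("degenerate circular mean: resultant length ",
            format(sqrt(s^2 + cc^2) / length(times)),
            " is below tolerance (antipodal or uniform inputs)")
  wrap_time(atan2(s, cc) / (2 * pi))
}

#' Circular standard deviation of prediction errors
#'
#' Maps signed errors (hours) to angles, computes the mean resultant length
#' `Rbar`, and returns `period/(2*pi) * sqrt(-2 * log(Rbar))` in hours -- the
#' standard circular SD. Zero when all errors are equal; grows without bound
#' as the errors spread around the circle.
#'
#' @param errors Numeric vector of signed errors in hours.
#' @param period Period length in hours (default 24).
#' @return Circular standard deviation in hours.
#' @export
circular_sd <- function(errors, period = 24) {
  check_finite(errors, "errors")
  if (length(errors) == 0L) stop_ct("errors must be non-empty")
  theta <- 2 * pi * errors / period
  rbar <- sqrt(mean(sin(theta))^2 + mean(cos(theta))^2)
  if (rbar <= 1e-12)
    stop_ct("circular SD undefined: mean resultant length is zero")
  period / (2 * pi) * sqrt(-2 * log(rbar))
}

#' Signed circular phase difference
#'
#' Difference between two phases accounting for periodicity: CT2 is 4 h ahead
#' of CT22, not 20 h behind. Positive values mean `phase_a` is ahead of
#' (later than) `phase_b` along the shorter arc.
#'
#' @param phase_a,phase_b Phases scaled to `[0, 1)`.
#' @param period Period length in hours (default 24).
#' @return Signed difference in hours, in `(-period/2, period/2]`.
#' @examples
#' phase_difference(2 / 24, 22 / 24)  # +4
#' @export
phase_difference <- function(phase_a, phase_b, period = 24) {
  circular_error(phase_a, phase_b, period)$signed_error
}

# Circular mean of signed hour-errors mapped back to (-period/2, period/2].
# Used to summarize the apparent phase shift of a condition's predictions.
signed_circular_mean <- function(errors, period = 24) {
  m <- circular_mean(wrap_time(errors / period))
  if (m > 0.5) m <- m - 1
  m * period
}
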