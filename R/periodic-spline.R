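# Periodic (cyclic cubic) regression splines of a signal versus time on the
# unit circle. The basis is mgcv's cyclic cubic regression spline with
# equispaced knots on [0, 1); with the small knot counts used here (3 by
# default, which constrains flexibility and resists noise) the fit is plain
# unpenalized least squares on that basis.

# Cache of mgcv smooth constructors, one per knot count. The basis depends
# only on n_knots, so rebuilding it per gene would be pure waste.
.cc_cache <- new.env(parent = emptyenv())

cyclic_smooth <- function(n_knots) {
  key <- as.character(n_knots)
  sm <- .cc_cache[[key]]
  if (is.null(sm)) {
    knots <- list(t = seq(0, 1, length.out = n_knots + 1))
    sm <- mgcv::smoothCon(mgcv::s(t, bs = "cc", k = n_knots + 1),
                          data = data.frame(t = knots$t), knots = knots,
                          absorb.cons = FALSE)[[1]]
    .cc_cache[[key]] <- sm
  }
  sm
}

# Design matrix of the cyclic basis at arbitrary times (wrapped internally).
cyclic_basis <- function(times, n_knots) {
  mgcv::PredictMat(cyclic_smooth(n_knots), data.frame(t = wrap_time(times)))
}

# Least-squares fit of every column of `values` (n_obs x n_series) against
# the shared cyclic basis at `times`. Returns coefficients (n_knots x
# n_series) and per-series residual RMSE. This is the fast path used when
# fitting thousands of genes that share one set of sampling times.
fit_periodic_matrix <- function(times, values, n_knots = 3) {
  check_finite(times, "times")
  check_finite(values, "values")
  values <- as.matrix(values)
  n <- length(times)
  if (nrow(values) != n) stop_ct("times and values have mismatched lengths")
  if (n < n_knots + 2)
    stop_ct("need at least n_knots + 2 = ", n_knots + 2,
            " observations to fit a periodic spline (got ", n, ")")
  B <- cyclic_basis(times, n_knots)
  qrB <- qr(B)
  if (qrB$rank < ncol(B))
    stop_ct("rank-deficient design: times do not span the circle ",
            "(all identical, or too few distinct values)")
  coefs <- qr.coef(qrB, values)
  fitted <- B %*% coefs
  rmse <- sqrt(colMeans((values - fitted)^2))
  list(coefficients = coefs, residual_rmse = rmse, n_obs = n)
}

#' Fit a periodic smoothing spline
#'
#' Fits a cyclic cubic regression spline with `n_knots` equispaced knots on
#' the unit circle to `values` observed at `times`, by unpenalized least
#' squares. The fitted function and its first two derivatives are continuous
#' across the period boundary. The residual root-mean-squared error (with
#' denominator `n_obs`) is stored as the noise scale `s` used by [snr()] and
#' by the fit-matrix scaling during training.
#'
#' @param times Numeric vector of times scaled to `[0, 1)` (wrapped if not).
#' @param values Numeric vector of observations, same length as `times`.
#' @param n_knots Number of equispaced knots on the circle (default 3).
#' @return An object of class `periodic_spline` with fields `n_knots`,
#'   `coefficients`, `residual_rmse`, `n_obs`.
#' @examples
#' t <- seq(0, 23) / 24
#' fit <- fit_periodic_spline(t, cos(2 * pi * t))
#' predict(fit, c(0, 0.25, 0.5))
#' @seealso [predict.periodic_spline()], [discretize_spline()], [peak_time()]
#' @export
fit_periodic_spline <- function(times, values, n_knots = 3) {
  f <- fit_periodic_matrix(wrap_time(times), matrix(values, ncol = 1), n_knots)
  new_periodic_spline(n_knots, drop(f$coefficients), f$residual_rmse, f$n_obs)
}

new_periodic_spline <- function(n_knots, coefficients, residual_rmse, n_obs) {
  structure(list(n_knots = n_knots,
                 coefficients = as.numeric(coefficients),
                 residual_rmse = as.numeric(residual_rmse),
                 n_obs = as.integer(n_obs)),
            class = "periodic_spline")
}

#' Evaluate a periodic spline fit
#'
#' @param object A `periodic_spline` fit.
#' @param t Numeric vector of times; wrapped onto `[0, 1)`, so
#'   `predict(fit, t)` equals `predict(fit, t + 1)`.
#' @param ... Unused.
#' @return Numeric vector of fitted values `f(t)`.
#' @export
predict.periodic_spline <- function(object, t, ...) {
  drop(cyclic_basis(t, object$n_knots) %*% object$coefficients)
}

#' @export
print.periodic_spline <- function(x, ...) {
  cat("Periodic spline fit:", x$n_knots, "knots,", x$n_obs,
      "observations, residual RMSE", format(x$residual_rmse, digits = 4), "\n")
  invisible(x)
}

#' Discretize a periodic spline fit
#'
#' Evaluates the fit on the regular grid `t = 0, 1/n_time, ...,
#' (n_time-1)/n_time`; these discretized profiles, scaled by residual noise,
#' are the rows of the matrix decomposed into sparse components during
#' training.
#'
#' @param fit A `periodic_spline` fit.
#' @param n_time Number of grid points (default 12).
#' @return Numeric vector of length `n_time`.
#' @export
discretize_spline <- function(fit, n_time = 12) {
  stopifnot(inherits(fit, "periodic_spline"))
  if (n_time < 2) stop_ct("n_time must be at least 2")
  predict(fit, (seq_len(n_time) - 1) / n_time)
}

#' Time of peak expression of a periodic fit
#'
#' Phase of a rhythmic profile, defined as the argmax of the fitted function
#' over the circle: a dense-grid scan refined by local continuous
#' optimization. Ties are broken toward the smallest time.
#'
#' @param fit A `periodic_spline` fit.
#' @param grid_size Number of grid points scanned (default 1440, i.e.
#'   1-minute resolution on a 24-h period).
#' @return Peak time in `[0, 1)`.
#' @export
peak_time <- function(fit, grid_size = 1440) {
  stopifnot(inherits(fit, "periodic_spline"))
  grid <- (seq_len(grid_size) - 1) / grid_size
  vals <- predict(fit, grid)
  if (diff(range(vals)) < 1e-12)
    stop_ct("phase undefined: fitted function is constant")
  if (diff(range(vals)) < 1e-6)
    warning("fitted range is tiny; peak time is poorly determined")
  i <- which.max(vals)  # first maximum = smallest t on ties
  refine_argmax(function(t) predict(fit, t), grid[i], 1 / grid_size)
}

# Golden-section style refinement of a circular argmax around grid point t0.
refine_argmax <- function(f, t0, half_width) {
  opt <- stats::optimize(f, lower = t0 - half_width, upper = t0 + half_width,
                         maximum = TRUE, tol = 1e-10)
  if (opt$objective >= f(t0)) wrap_time(opt$maximum) else wrap_time(t0)
}
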