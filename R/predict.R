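# Maximum-likelihood prediction of circadian time: single samples, groups of
# samples a known time apart, and ensembles of predictors.

# Component spline means on the default evaluation grid, cached per predictor
# object via an environment attribute-free memo keyed by grid size.
spline_means_on_grid <- function(object, grid) {
  matrix(vapply(object$spc_splines, function(s) predict(s, grid),
                numeric(length(grid))),
         nrow = length(grid))                        # grid x nSPC
}

#' Log-likelihood of component scores at a candidate time
#'
#' Sum over components of Gaussian log-densities with mean equal to the
#' component's spline fit at `t` and SD equal to its training residual SD:
#' the `L(t | x)` maximized by all predictions.
#'
#' @param object A `circatime` predictor.
#' @param spc_values Numeric vector of component scores (length `nSPC`).
#' @param t Time(s) in `[0, 1)`; vectorized.
#' @return Log-likelihood value(s).
#' @export
log_likelihood <- function(object, spc_values, t) {
  stopifnot(inherits(object, "circatime"))
  G <- spline_means_on_grid(object, wrap_time(t))
  rowSums(matrix(vapply(seq_along(object$spc_sd), function(k)
    stats::dnorm(spc_values[k], G[, k], object$spc_sd[k], log = TRUE),
    numeric(length(t))), nrow = length(t)))
}

new_prediction <- function(t_hat, grid, loglik, source) {
  structure(list(t_hat = t_hat, grid = grid, loglik = loglik,
                 source = source),
            class = "ct_prediction")
}

#' @export
print.ct_prediction <- function(x, ...) {
  cat(sprintf("Circadian time prediction (%s): t = %.4f (%.2f h on 24 h)\n",
              x$source, x$t_hat, x$t_hat * 24))
  invisible(x)
}

# Shared argmax: dense grid scan (ties -> smallest t) plus local refinement
# of the continuous profile.
profile_argmax <- function(profile_fun, grid_size) {
  grid <- (seq_len(grid_size) - 1) / grid_size
  ll <- profile_fun(grid)
  i <- which.max(ll)
  t_hat <- refine_argmax(profile_fun, grid[i], 1 / grid_size)
  list(t_hat = t_hat, grid = grid, loglik = ll)
}

predict_from_scores <- function(object, z, source = "single") {
  p <- profile_argmax(function(t) log_likelihood(object, z, t),
                      object$config$grid_size)
  new_prediction(p$t_hat, p$grid, p$loglik, source)
}

#' Predict circadian time from expression
#'
#' Projects each sample onto the predictor's sparse components and maximizes
#' the log-likelihood of the scores over times on the circle (dense grid plus
#' local refinement; ties broken toward the smallest time).
#'
#' With `tau` supplied, the columns of `newdata` are treated as one *group*
#' of samples from the same individual taken a known time apart: `tau[i]` is
#' the time of sample `i` relative to the group's reference sample (at least
#' one `tau` must be 0). The group log-likelihood is the sum of the
#' per-sample log-likelihoods evaluated at `(t + tau[i]) mod 1`, and the
#' returned time estimates the reference sample's time. With a single sample
#' and `tau = 0` this reduces exactly to the single-sample prediction.
#'
#' @param object A `circatime` predictor.
#' @param newdata Named numeric vector (one sample) or matrix of genes by
#'   samples with gene row names; must cover the predictor's genes.
#' @param tau Optional numeric vector of within-group time offsets, scaled to
#'   the period, one per column of `newdata`.
#' @param profile If `TRUE`, return `ct_prediction` objects (with the
#'   log-likelihood profile over the grid) instead of bare times.
#' @param ... Unused.
#' @return Default: named numeric vector of predicted times in `[0, 1)` (one
#'   per sample), or a single `ct_prediction` for a group. With
#'   `profile = TRUE`: a list of `ct_prediction` objects.
#' @examples
#' coh <- generate_cohort(synth_config(n_individuals = 10, n_genes = 200,
#'                                     rhythmic_fraction = 0.1, seed = 1))
#' fit <- circatime(coh$expr, coh$meta)
#' predict(fit, coh$expr[, 1:2])                 # two single samples
#' predict(fit, coh$expr[, 1:2], tau = c(0, 0.5))  # one two-sample group
#' @export
predict.circatime <- function(object, newdata, tau = NULL, profile = FALSE,
                              ...) {
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, ncol = 1,
                      dimnames = list(names(newdata), "sample"))
  if (!is.null(tau)) return(predict_group(object, newdata, tau))
  Z <- project_spcs(newdata, object$spc_model)
  preds <- lapply(seq_len(ncol(Z)), function(j)
    predict_from_scores(object, Z[, j]))
  names(preds) <- colnames(newdata)
  if (profile) return(preds)
  vapply(preds, function(p) p$t_hat, numeric(1))
}

#' Joint prediction for a group of samples taken a known time apart
#'
#' @param object A `circatime` predictor.
#' @param samples Matrix of genes by group samples (gene row names).
#' @param tau Time offsets of each sample relative to the reference sample
#'   (scaled units, wrapped to `[0, 1)`); at least one must be 0.
#' @return A `ct_prediction` for the reference sample's time.
#' @seealso [predict.circatime()] which dispatches here when `tau` is given.
#' @export
predict_group <- function(object, samples, tau) {
  stopifnot(inherits(object, "circatime"))
  if (is.null(dim(samples)))
    samples <- matrix(samples, ncol = 1, dimnames = list(names(samples), NULL))
  if (ncol(samples) == 0) stop_ct("empty group")
  if (length(tau) != ncol(samples))
    stop_ct("tau must have one offset per group sample")
  tau <- wrap_time(tau)
  if (!any(tau == 0))
    stop_ct("one group sample must be the reference (tau = 0)")
  Z <- project_spcs(samples, object$spc_model)
  pfun <- function(t) {
    Reduce(`+`, lapply(seq_along(tau), function(i)
      log_likelihood(object, Z[, i], wrap_time(t + tau[i]))))
  }
  p <- profile_argmax(pfun, object$config$grid_size)
  new_prediction(p$t_hat, p$grid, p$loglik, "group")
}

#' Build within-individual sample groups at a requested spacing
#'
#' Greedily pairs (or chains) each individual's samples so that consecutive
#' group members are `spacing` hours apart within `tolerance`; samples are
#' scanned in time order and each sample enters at most one group. The first
#' member of each group is the reference (`tau = 0`). Group membership is
#' intended for testing only -- training never sees it.
#'
#' @param meta Sample metadata with columns `sample_id`, `individual_id`, and
#'   `time` (scaled `[0, 1)`).
#' @param spacing Hours between consecutive samples in a group (e.g. 12 for
#'   antiphase pairs; use 6 with `size = 3` for three samples over 12 h).
#' @param size Samples per group (default 2).
#' @param tolerance Matching tolerance in hours (default 0.5).
#' @param period Period in hours (default 24).
#' @return List of groups, each a list with `sample_ids`, `taus` (scaled,
#'   first is 0) and `individual_id`. Individuals without compatible samples
#'   contribute no groups.
#' @export
build_groups <- function(meta, spacing, size = 2, tolerance = 0.5,
                         period = 24) {
  meta <- as.data.frame(meta)
  groups <- list()
  for (ind in unique(meta$individual_id)) {
    m <- meta[meta$individual_id == ind, ]
    m <- m[order(m$time), ]
    hours <- m$time * period
    used <- rep(FALSE, nrow(m))
    for (i in seq_len(nrow(m))) {
      if (used[i]) next
      chain <- i
      ok <- TRUE
      for (step in seq_len(size - 1)) {
        target <- hours[chain[length(chain)]] + spacing
        cand <- which(!used & abs(hours - target) <= tolerance)
        cand <- setdiff(cand, chain)
        if (length(cand) == 0) {
          ok <- FALSE
          break
        }
        chain <- c(chain, cand[1])
      }
      if (ok && length(chain) == size) {
        used[chain] <- TRUE
        groups[[length(groups) + 1]] <-
          list(sample_ids = as.character(m$sample_id[chain]),
               taus = wrap_time((hours[chain] - hours[chain[1]]) / period),
               individual_id = ind)
      }
    }
  }
  groups
}

#' Ensemble prediction by summed log-likelihood
#'
#' Sums the log-likelihood profiles of several predictors over a shared time
#' grid (all members weighted equally) and maximizes the sum.
#'
#' @param predictors Non-empty list of `circatime` predictors.
#' @param x Named expression vector (or one-column matrix) covering every
#'   predictor's genes.
#' @return A `ct_prediction` with source `"ensemble"`.
#' @export
ensemble_predict_loglik <- function(predictors, x) {
  if (length(predictors) == 0) stop_ct("empty predictor list")
  zs <- lapply(predictors, function(p) drop(project_spcs(x, p$spc_model)))
  pfun <- function(t) {
    Reduce(`+`, Map(function(p, z) log_likelihood(p, z, t), predictors, zs))
  }
  p <- profile_argmax(pfun, predictors[[1]]$config$grid_size)
  new_prediction(p$t_hat, p$grid, p$loglik, "ensemble")
}

#' Ensemble prediction by circular mean of member predictions
#'
#' Combines member predictions as the circular mean of their predicted
#' times -- the simpler of the two ensembling rules, and the one used for all
#' ensembles in the downstream analyses.
#'
#' @param predictions List of `ct_prediction` objects, or a numeric vector of
#'   predicted times in `[0, 1)`.
#' @return A `ct_prediction` with source `"ensemble"` and no profile.
#' @export
ensemble_predict_circmean <- function(predictions) {
  if (length(predictions) == 0) stop_ct("empty prediction list")
  t_hats <- if (is.numeric(predictions)) predictions
    else vapply(predictions, function(p) p$t_hat, numeric(1))
  new_prediction(circular_mean(t_hats), grid = NULL, loglik = NULL,
                 source = "ensemble")
}
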