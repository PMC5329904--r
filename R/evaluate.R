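# Cross-validation harnesses, the SNR statistic, and error summaries.

#' Signal-to-noise ratio of a periodic fit
#'
#' Peak-to-trough range of the fitted periodic function divided by the fit's
#' residual RMSE (floored): `SNR = (max f - min f) / s`. Zero for a constant
#' profile; large for strongly rhythmic, low-noise genes.
#'
#' @param fit A `periodic_spline` fit.
#' @param grid_size Grid used to evaluate the range (default 512).
#' @param floor Lower bound on the RMSE denominator (default 1e-6).
#' @return Non-negative scalar.
#' @export
snr <- function(fit, grid_size = 512, floor = 1e-6) {
  stopifnot(inherits(fit, "periodic_spline"))
  vals <- predict(fit, (seq_len(grid_size) - 1) / grid_size)
  diff(range(vals)) / max(fit$residual_rmse, floor)
}

#' Assign individuals to cross-validation folds
#'
#' Individuals (never single samples) are shuffled under the seed and dealt
#' round-robin into `k` folds, so all samples from an individual share a
#' fold and no information leaks between training and test sets through
#' within-individual correlation.
#'
#' @param meta Sample metadata with `sample_id` and `individual_id`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold labels, one per row of `meta`.
#' @export
make_folds <- function(meta, k = 10, seed = 1) {
  meta <- as.data.frame(meta)
  inds <- unique(as.character(meta$individual_id))
  if (length(inds) < k)
    stop_ct("need at least k = ", k, " individuals (got ", length(inds), ")")
  shuffled <- with_seed(seed, sample(inds))
  fold_of <- stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  unname(fold_of[as.character(meta$individual_id)])
}

cv_summary <- function(records, period = 24) {
  list(n = nrow(records),
       median_abs_error = stats::median(records$abs_error),
       iqr_abs_error = stats::IQR(records$abs_error),
       circular_sd = circular_sd(records$signed_error, period))
}

new_cv_result <- function(records, period = 24, scheme = "cv", extra = NULL) {
  out <- c(list(records = records, summary = cv_summary(records, period),
                scheme = scheme), extra)
  class(out) <- "ct_cv"
  out
}

#' @export
print.ct_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Cross-validation (%s): %d predictions\n  median |error| %.2f h, IQR %.2f h, circular SD %.2f h\n",
    x$scheme, s$n, s$median_abs_error, s$iqr_abs_error, s$circular_sd))
  invisible(x)
}

record_predictions <- function(meta, predicted, fold, period = 24) {
  err <- circular_error(predicted, meta$time, period)
  data.frame(sample_id = as.character(meta$sample_id),
             individual_id = as.character(meta$individual_id),
             fold = fold,
             observed = meta$time,
             predicted = predicted,
             signed_error = err$signed_error,
             abs_error = err$absolute_error,
             stringsAsFactors = FALSE)
}

#' Tenfold cross-validation grouped by individual
#'
#' Trains a predictor on nine folds and predicts the held-out fold's samples,
#' for each fold in turn; all samples from an individual stay in one fold.
#'
#' @param expr Genes-by-samples matrix.
#' @param meta Sample metadata (`sample_id`, `individual_id`, `time`; other
#'   columns are carried through to the records).
#' @param sumabsv,nSPC Training parameters (defaults 2 and 2).
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment.
#' @param keep_models If `TRUE`, the per-fold predictors are returned too.
#' @param period Period in hours (default 24).
#' @param ... Passed to [circatime()].
#' @return A `ct_cv` object: per-sample `records` (observed and predicted
#'   times, signed/absolute error in hours) and a `summary` (median absolute
#'   error, IQR, circular SD) recomputable from the records.
#' @export
cv_tenfold <- function(expr, meta, sumabsv = 2, nSPC = 2, k = 10, seed = 1,
                       keep_models = FALSE, period = 24, ...) {
  meta <- as.data.frame(meta)
  folds <- make_folds(meta, k, seed)
  records <- NULL
  models <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- circatime(expr[, as.character(meta$sample_id[!test]), drop = FALSE],
                     meta[!test, ], sumabsv = sumabsv, nSPC = nSPC, ...)
    pred <- predict(fit, expr[, as.character(meta$sample_id[test]),
                              drop = FALSE])
    records <- rbind(records,
                     cbind(record_predictions(meta[test, ], unname(pred), f,
                                              period),
                           meta[test, setdiff(names(meta),
                                              c("sample_id", "individual_id",
                                                "time")), drop = FALSE]))
    if (keep_models) models[[f]] <- fit
  }
  rownames(records) <- NULL
  new_cv_result(records, period, "tenfold",
                c(list(folds = folds),
                  if (keep_models) list(models = models)))
}

#' Cross-validated parameter sweep
#'
#' Runs [cv_tenfold()] over a grid of `sumabsv` and `nSPC` values and
#' tabulates the error summaries, mirroring the usual tuning plot.
#'
#' @param expr,meta As in [cv_tenfold()].
#' @param sumabsv_grid,nSPC_grid Parameter values to sweep.
#' @param ... Passed to [cv_tenfold()].
#' @return Data frame with one row per parameter pair: `sumabsv`, `nSPC`,
#'   `median_abs_error`, `iqr_abs_error`, `circular_sd`.
#' @export
cv_sweep <- function(expr, meta, sumabsv_grid = c(1, 2, 3),
                     nSPC_grid = c(1, 2, 3), ...) {
  grid <- expand.grid(sumabsv = sumabsv_grid, nSPC = nSPC_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    s <- cv_tenfold(expr, meta, sumabsv = grid$sumabsv[i],
                    nSPC = grid$nSPC[i], ...)$summary
    data.frame(sumabsv = grid$sumabsv[i], nSPC = grid$nSPC[i],
               median_abs_error = s$median_abs_error,
               iqr_abs_error = s$iqr_abs_error, circular_sd = s$circular_sd)
  })
  do.call(rbind, res)
}

#' Grouped cross-validation with multi-sample test groups
#'
#' Identical folds and training to [cv_tenfold()], but each held-out fold is
#' additionally predicted in within-individual groups of `size` samples
#' spaced `spacing` hours apart (group structure is used only at test time,
#' never in training). Single-sample predictions for the same folds are
#' returned alongside for a paired comparison.
#'
#' @param expr,meta,sumabsv,nSPC,k,seed,period,... As in [cv_tenfold()].
#' @param spacing Hours between consecutive group samples (default 12).
#' @param size Samples per group (default 2).
#' @param tolerance Spacing tolerance in hours (default 0.5).
#' @return List of class `ct_cv_group` with `single` and `group` (`ct_cv`
#'   objects; group records are one row per group, evaluated at the
#'   reference sample).
#' @export
cv_group_tenfold <- function(expr, meta, spacing = 12, size = 2,
                             tolerance = 0.5, sumabsv = 2, nSPC = 2, k = 10,
                             seed = 1, period = 24, ...) {
  meta <- as.data.frame(meta)
  folds <- make_folds(meta, k, seed)
  single_rec <- NULL
  group_rec <- NULL
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- circatime(expr[, as.character(meta$sample_id[!test]), drop = FALSE],
                     meta[!test, ], sumabsv = sumabsv, nSPC = nSPC, ...)
    m_test <- meta[test, ]
    pred <- predict(fit, expr[, as.character(m_test$sample_id), drop = FALSE])
    single_rec <- rbind(single_rec,
                        record_predictions(m_test, unname(pred), f, period))
    groups <- build_groups(m_test, spacing, size, tolerance, period)
    for (g in groups) {
      p <- predict_group(fit, expr[, g$sample_ids, drop = FALSE], g$taus)
      ref <- m_test[m_test$sample_id == g$sample_ids[1], ]
      group_rec <- rbind(group_rec,
                         record_predictions(ref, p$t_hat, f, period))
    }
  }
  if (is.null(group_rec))
    stop_ct("no groups could be built at spacing ", spacing, " h")
  structure(list(single = new_cv_result(single_rec, period, "tenfold"),
                 group = new_cv_result(group_rec, period,
                                       paste0("group-", size, "x", spacing,
                                              "h"))),
            class = "ct_cv_group")
}

#' @export
print.ct_cv_group <- function(x, ...) {
  cat(sprintf("Single samples: median |error| %.2f h (n = %d)\n",
              x$single$summary$median_abs_error, x$single$summary$n))
  cat(sprintf("Groups:         median |error| %.2f h (n = %d)\n",
              x$group$summary$median_abs_error, x$group$summary$n))
  invisible(x)
}

#' Leave-one-study-out evaluation with per-condition phase delays
#'
#' For each study in turn, trains a predictor on the *control* samples of the
#' remaining studies and predicts every sample (all conditions) of the
#' held-out study. Each condition's apparent phase delay is estimated as the
#' circular mean of the signed prediction errors; a positive delay means the
#' condition's samples look later than the clock time says.
#'
#' @param expr,meta As in [cv_tenfold()]; `meta` must carry `study_id` and
#'   `condition` columns.
#' @param control Label of the control condition (default `"control"`).
#' @param sumabsv,nSPC,period,... As in [cv_tenfold()].
#' @return List of class `ct_cv_loso`: per-study `ct_cv` results in
#'   `studies`, and `conditions`, a data frame with per study and condition
#'   the n, median absolute error, circular SD, and phase delay (hours).
#' @export
cv_leave_one_study_out <- function(expr, meta, control = "control",
                                   sumabsv = 2, nSPC = 2, period = 24, ...) {
  meta <- as.data.frame(meta)
  studies <- unique(as.character(meta$study_id))
  if (length(studies) < 2) stop_ct("need at least 2 studies")
  out <- list()
  cond_rows <- NULL
  for (s in studies) {
    train <- meta$study_id != s & meta$condition == control
    test <- meta$study_id == s
    fit <- circatime(expr[, as.character(meta$sample_id[train]),
                          drop = FALSE],
                     meta[train, ], sumabsv = sumabsv, nSPC = nSPC, ...)
    m_test <- meta[test, ]
    pred <- predict(fit, expr[, as.character(m_test$sample_id), drop = FALSE])
    rec <- cbind(record_predictions(m_test, unname(pred), NA, period),
                 condition = as.character(m_test$condition),
                 study_id = s, stringsAsFactors = FALSE)
    out[[s]] <- new_cv_result(rec, period, paste0("loso-", s))
    for (cond in unique(rec$condition)) {
      r <- rec[rec$condition == cond, ]
      cond_rows <- rbind(cond_rows, data.frame(
        study_id = s, condition = cond, n = nrow(r),
        median_abs_error = stats::median(r$abs_error),
        circular_sd = circular_sd(r$signed_error, period),
        phase_delay = signed_circular_mean(r$signed_error, period),
        stringsAsFactors = FALSE))
    }
  }
  structure(list(studies = out, conditions = cond_rows),
            class = "ct_cv_loso")
}

#' @export
print.ct_cv_loso <- function(x, ...) {
  cat("Leave-one-study-out evaluation\n")
  print(x$conditions, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Condition phase shift from clock-gene spline peaks
#'
#' Alternative estimator of a condition's phase shift: fits a periodic spline
#' per gene within each condition and takes the circular mean, over genes, of
#' the peak-time differences. Complements the prediction-error estimator in
#' [cv_leave_one_study_out()].
#'
#' @param expr,meta As elsewhere; `meta` must carry `condition`.
#' @param genes Genes whose peak shifts are averaged.
#' @param condition_a,condition_b The two condition labels (shift of `a`
#'   relative to `b`).
#' @param n_knots Spline knots (default 3).
#' @param period Period in hours (default 24).
#' @return Signed shift in hours, in `(-period/2, period/2]`.
#' @export
phase_shift_by_splines <- function(expr, meta, genes, condition_a,
                                   condition_b, n_knots = 3, period = 24) {
  meta <- as.data.frame(meta)
  peak_of <- function(cond, g) {
    m <- meta[meta$condition == cond, ]
    peak_time(fit_periodic_spline(m$time,
                                  expr[g, as.character(m$sample_id)],
                                  n_knots))
  }
  shifts <- vapply(genes, function(g)
    phase_difference(peak_of(condition_a, g), peak_of(condition_b, g),
                     period), numeric(1))
  signed_circular_mean(shifts, period)
}

#' Personal leave-one-sample-out cross-validation under universal guidance
#'
#' Uses the same individual-grouped folds as [cv_tenfold()]. For each fold a
#' universal predictor is trained on the other folds; for each individual in
#' the fold and each held-out sample, a personal predictor is trained on the
#' individual's remaining samples restricted to that universal predictor's
#' genes, and the held-out sample is predicted by the universal predictor,
#' the personal predictor, and their circular-mean ensemble. The guiding
#' universal predictor never sees the held-out individual's fold.
#'
#' @param expr,meta,sumabsv,nSPC,k,seed,period As in [cv_tenfold()].
#' @param min_samples Individuals with fewer samples than `min_samples + 1`
#'   are skipped with a message (default 4 training samples).
#' @param ... Passed to [circatime()].
#' @return List of class `ct_cv_personal`: `records` with one row per
#'   held-out sample carrying aligned `universal`, `personal` and `ensemble`
#'   predictions and errors, and `summary`, a per-predictor table.
#' @export
cv_personal_loo <- function(expr, meta, sumabsv = 2, nSPC = 2, k = 10,
                            seed = 1, min_samples = 4, period = 24, ...) {
  meta <- as.data.frame(meta)
  folds <- make_folds(meta, k, seed)
  records <- NULL
  for (f in seq_len(k)) {
    test <- folds == f
    universal <- circatime(expr[, as.character(meta$sample_id[!test]),
                                drop = FALSE],
                           meta[!test, ], sumabsv = sumabsv, nSPC = nSPC, ...)
    for (ind in unique(as.character(meta$individual_id[test]))) {
      m_ind <- meta[test & meta$individual_id == ind, ]
      if (nrow(m_ind) < min_samples + 1) {
        message("skipping individual ", ind, ": only ", nrow(m_ind),
                " samples")
        next
      }
      for (i in seq_len(nrow(m_ind))) {
        m_train <- m_ind[-i, ]
        guided <- shrink_training_set(expr, m_train, universal, ind)
        personal <- suppressWarnings(
          train_personal(guided, sumabsv = sumabsv, nSPC = nSPC,
                         min_samples = min_samples, ...))
        x <- expr[, as.character(m_ind$sample_id[i])]
        names(x) <- rownames(expr)
        tu <- unname(predict(universal, x))
        tp <- unname(predict(personal, x))
        te <- circular_mean(c(tu, tp))
        obs <- m_ind$time[i]
        err <- function(p) circular_error(p, obs, period)
        records <- rbind(records, data.frame(
          sample_id = as.character(m_ind$sample_id[i]),
          individual_id = ind, fold = f, observed = obs,
          universal = tu, personal = tp, ensemble = te,
          universal_abs_error = err(tu)$absolute_error,
          personal_abs_error = err(tp)$absolute_error,
          ensemble_abs_error = err(te)$absolute_error,
          universal_signed_error = err(tu)$signed_error,
          personal_signed_error = err(tp)$signed_error,
          ensemble_signed_error = err(te)$signed_error,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(records)) stop_ct("no individual had enough samples")
  summ <- do.call(rbind, lapply(c("universal", "personal", "ensemble"),
    function(w) data.frame(
      predictor = w,
      median_abs_error = stats::median(records[[paste0(w, "_abs_error")]]),
      circular_sd = circular_sd(records[[paste0(w, "_signed_error")]],
                                period),
      stringsAsFactors = FALSE)))
  structure(list(records = records, summary = summ),
            class = "ct_cv_personal")
}

#' @export
print.ct_cv_personal <- function(x, ...) {
  cat("Personal leave-one-sample-out cross-validation (",
      nrow(x$records), " predictions)\n", sep = "")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
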