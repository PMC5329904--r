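#' Train a circadian-time predictor
#'
#' Fits the full training pipeline on a cohort of expression profiles with
#' known times of day: (1) a periodic smoothing spline of each gene's
#' expression versus time on the unit circle; (2) discretization of each
#' spline at `n_time` equispaced points and scaling by the spline's residual
#' RMSE (so high signal-to-noise genes dominate); (3) sparse principal
#' components of the scaled fit matrix under an L1 budget of `sumabsv` per
#' component, selecting a small set of informative genes; (4) a periodic
#' spline of each component's score versus time, with residual SD, which
#' together define the Gaussian log-likelihood `L(t | x)` maximized at
#' prediction time.
#'
#' @param expr Numeric matrix of log-scale expression, genes in rows (row
#'   names are gene identifiers), samples in columns (column names are sample
#'   identifiers).
#' @param meta Data frame of sample metadata with columns `sample_id` and
#'   `time` (observed time of day scaled to `[0, 1)`); one row per column of
#'   `expr`. Extra columns (`individual_id`, `study_id`, `condition`) are
#'   carried by the cross-validation harnesses but not used in fitting.
#' @param sumabsv L1 budget on each component's gene loadings (default 2);
#'   larger values admit more genes.
#' @param nSPC Number of sparse components used for prediction (default 2).
#' @param n_knots Knots of every periodic spline (default 3; few knots
#'   constrain flexibility and resist noise).
#' @param n_time Discretization points for the fit matrix (default 12).
#' @param grid_size Grid resolution of the likelihood argmax at prediction
#'   time (default 1440, i.e. 1 minute on a 24-h period).
#' @param sd_floor Lower bound on each component's residual SD (default
#'   1e-6), preventing infinite likelihood on perfect fits.
#' @return An object of class `circatime`: the sparse component model
#'   restricted to genes with nonzero loading, per-component spline fits and
#'   residual SDs, the training scores and times, and the configuration.
#' @examples
#' coh <- generate_cohort(synth_config(n_individuals = 10, n_genes = 200,
#'                                     rhythmic_fraction = 0.1, seed = 1))
#' fit <- circatime(coh$expr, coh$meta)
#' fit
#' predict(fit, coh$expr[, 1:3])
#' @seealso [predict.circatime()], [cv_tenfold()], [write_model()]
#' @export
circatime <- function(expr, meta, sumabsv = 2, nSPC = 2, n_knots = 3,
                      n_time = 12, grid_size = 1440, sd_floor = 1e-6) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop_ct("expr must have gene row names and sample column names")
  check_finite(expr, "expr")
  meta <- as.data.frame(meta)
  if (!all(c("sample_id", "time") %in% names(meta)))
    stop_ct("meta must have columns sample_id and time")
  if (!all(meta$sample_id %in% colnames(expr)))
    stop_ct("meta references samples absent from expr")
  expr <- expr[, as.character(meta$sample_id), drop = FALSE]
  times <- wrap_time(meta$time)
  if (length(unique(round(times, 10))) < 2)
    stop_ct("degenerate time coverage: need at least 2 distinct times")

  gene_var <- apply(expr, 1, stats::var)
  dropped <- rownames(expr)[gene_var == 0]
  if (length(dropped) > 0) {
    message("dropping ", length(dropped), " zero-variance gene(s)")
    expr <- expr[gene_var > 0, , drop = FALSE]
  }
  if (nrow(expr) == 0) stop_ct("no genes with nonzero variance")

  # steps 1-2: per-gene periodic splines, discretized and noise-scaled
  fits <- fit_periodic_matrix(times, t(expr), n_knots)
  grid12 <- (seq_len(n_time) - 1) / n_time
  D <- cyclic_basis(grid12, n_knots) %*% fits$coefficients  # n_time x genes
  Xs <- scale_fit_matrix(D, fits$residual_rmse)
  colnames(Xs) <- rownames(expr)

  # step 3: sparse components; keep only the genes that enter the predictor
  spc_all <- compute_spcs(Xs, sumabsv, nSPC, gene_ids = rownames(expr))
  sel <- rowSums(spc_all$loadings != 0) > 0
  model <- structure(list(loadings = spc_all$loadings[sel, , drop = FALSE],
                          gene_ids = rownames(expr)[sel],
                          singular_values = spc_all$singular_values,
                          sumabsv = sumabsv, nSPC = nSPC),
                     class = "spc_model")

  # step 4: spline of each component's score versus time, plus residual SD
  scores <- project_spcs(expr[model$gene_ids, , drop = FALSE], model)
  sfits <- fit_periodic_matrix(times, t(scores), n_knots)
  spc_splines <- lapply(seq_len(nSPC), function(k)
    new_periodic_spline(n_knots, sfits$coefficients[, k],
                        sfits$residual_rmse[k], sfits$n_obs))
  spc_sd <- pmax(sfits$residual_rmse, sd_floor)

  structure(list(spc_model = model,
                 spc_splines = spc_splines,
                 spc_sd = as.numeric(spc_sd),
                 config = list(sumabsv = sumabsv, nSPC = nSPC,
                               n_knots = n_knots, n_time = n_time,
                               grid_size = grid_size, sd_floor = sd_floor),
                 dropped_genes = dropped,
                 train_times = times,
                 train_scores = scores,
                 train_sample_ids = as.character(meta$sample_id),
                 n_samples = ncol(expr),
                 call = match.call()),
            class = "circatime")
}

#' Genes selected by a predictor
#'
#' @param object A `circatime` predictor.
#' @return Character vector of genes with nonzero loading on any component.
#' @export
predictor_genes <- function(object) {
  stopifnot(inherits(object, "circatime"))
  object$spc_model$gene_ids
}

#' @export
print.circatime <- function(x, ...) {
  cat("Circadian time predictor\n")
  cat("  genes selected:", length(predictor_genes(x)),
      " components:", x$config$nSPC,
      " (sumabsv =", paste0(format(x$config$sumabsv), ")"), "\n")
  cat("  trained on", x$n_samples, "samples\n")
  invisible(x)
}

#' @export
summary.circatime <- function(object, ...) {
  k <- object$config$nSPC
  tab <- data.frame(
    component = paste0("SPC", seq_len(k)),
    n_genes = colSums(object$spc_model$loadings != 0),
    peak_time = vapply(object$spc_splines, peak_time, numeric(1)),
    residual_sd = object$spc_sd,
    snr = vapply(object$spc_splines, snr, numeric(1)),
    row.names = NULL)
  out <- list(n_genes = length(predictor_genes(object)),
              n_samples = object$n_samples,
              config = object$config, components = tab)
  class(out) <- "summary.circatime"
  out
}

#' @export
print.summary.circatime <- function(x, ...) {
  cat("Circadian time predictor:", x$n_genes, "genes,",
      x$config$nSPC, "components,", x$n_samples, "training samples\n\n")
  print(x$components, digits = 3)
  invisible(x)
}

#' @export
coef.circatime <- function(object, ...) object$spc_model$loadings

#' Plot component scores against time
#'
#' Shows each sparse component's training scores versus observed time with
#' its periodic spline fit overlaid -- the fitted means of the prediction
#' likelihood.
#'
#' @param x A `circatime` predictor (with training data attached; predictors
#'   restored by [read_model()] carry no scores and cannot be plotted).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.circatime <- function(x, ...) {
  if (is.null(x$train_scores))
    stop_ct("predictor carries no training scores (restored from file?)")
  k <- x$config$nSPC
  old <- graphics::par(mfrow = c(1, k))
  on.exit(graphics::par(old))
  grid <- seq(0, 1, length.out = 200)
  for (j in seq_len(k)) {
    graphics::plot(x$train_times * 24, x$train_scores[j, ],
                   xlab = "time (h)", ylab = paste0("SPC", j, " score"), ...)
    graphics::lines(grid * 24, predict(x$spc_splines[[j]], grid), lwd = 2)
  }
  invisible(x)
}

#' Predicted times for the training samples
#'
#' @param object A `circatime` predictor with training scores attached.
#' @param ... Unused.
#' @return Named vector of predicted times in `[0, 1)` for each training
#'   sample (in-sample; for honest error estimates use [cv_tenfold()]).
#' @export
fitted.circatime <- function(object, ...) {
  if (is.null(object$train_scores))
    stop_ct("predictor carries no training scores")
  p <- apply(object$train_scores, 2, function(z)
    predict_from_scores(object, z)$t_hat)
  names(p) <- object$train_sample_ids
  p
}

#' In-sample circular residuals
#'
#' @param object A `circatime` predictor with training data attached.
#' @param period Period in hours (default 24).
#' @param ... Unused.
#' @return Signed circular errors (hours) of the in-sample predictions.
#' @export
residuals.circatime <- function(object, period = 24, ...) {
  p <- fitted(object)
  stats::setNames(circular_error(p, object$train_times, period)$signed_error,
                  names(p))
}

#' Simulate expression consistent with a fitted predictor
#'
#' Draws component scores from the predictor's own model -- spline mean at
#' the requested time plus Gaussian noise with the component's residual SD --
#' and lifts them back to gene space through the pseudo-inverse of the
#' loadings, so that projecting a simulated sample reproduces the simulated
#' scores exactly. With `noise_sd_scale = 0` the sample generated at time `t`
#' sits exactly on the fitted spline means.
#'
#' @param object A `circatime` predictor.
#' @param nsim Number of samples per time point (default 1).
#' @param seed Optional integer seed.
#' @param times Times in `[0, 1)` at which to simulate (default: 8 equispaced).
#' @param noise_sd_scale Multiplier on the residual SDs (default 1).
#' @param ... Unused.
#' @return Matrix of genes (the predictor's genes) by `nsim * length(times)`
#'   samples, with the generating times in attribute `"times"`.
#' @export
simulate.circatime <- function(object, nsim = 1, seed = NULL,
                               times = (0:7) / 8, noise_sd_scale = 1, ...) {
  draw <- function() {
    tt <- rep(times, each = nsim)
    G <- vapply(object$spc_splines, function(s) predict(s, tt),
                numeric(length(tt)))        # samples x nSPC means
    Z <- G + matrix(stats::rnorm(length(G), 0,
                                 rep(object$spc_sd * noise_sd_scale,
                                     each = length(tt))),
                    nrow = length(tt))
    V <- object$spc_model$loadings
    X <- V %*% solve(crossprod(V), t(Z))    # project_spcs(X) == t(Z)
    dimnames(X) <- list(object$spc_model$gene_ids,
                        paste0("sim", seq_len(ncol(X))))
    attr(X, "times") <- tt
    X
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
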