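test_that("snr is range over residual noise", {
  t <- rep((0:11) / 12, 4)
  set.seed(51)
  flat <- fit_periodic_spline(t, rnorm(48, 5, 0.5))
  expect_lt(snr(flat), 2)  # no signal: only noise-level wiggle in the fit
  expect_equal(snr(fit_periodic_spline(t, rep(2, 48))), 0)
  # sinusoid amplitude A, noise sigma: SNR ~ 2A/sigma
  A <- 1.5; sigma <- 0.5
  vals <- vapply(1:10, function(s) {
    set.seed(s)
    snr(fit_periodic_spline(t, A * cos(2 * pi * t) + rnorm(48, 0, sigma)))
  }, numeric(1))
  expect_equal(mean(vals), 2 * A / sigma, tolerance = 0.1)
  # doubling the noise halves the SNR in expectation
  vals2 <- vapply(1:10, function(s) {
    set.seed(s)
    snr(fit_periodic_spline(t, A * cos(2 * pi * t) + rnorm(48, 0, 2 * sigma)))
  }, numeric(1))
  expect_equal(mean(vals) / mean(vals2), 2, tolerance = 0.25)
})

test_that("folds group individuals, deal evenly, and are seed-reproducible", {
  meta <- data.frame(sample_id = paste0("s", 1:480),
                     individual_id = rep(sprintf("I%02d", 1:60), each = 8))
  f <- make_folds(meta, k = 10, seed = 4)
  expect_equal(unname(table(f)), rep(48, 10), ignore_attr = TRUE)
  expect_identical(f, make_folds(meta, k = 10, seed = 4))
  expect_false(identical(f, make_folds(meta, k = 10, seed = 5)))
  # no individual spans folds
  spans <- tapply(f, meta$individual_id, function(x) length(unique(x)))
  expect_true(all(spans == 1))
  expect_error(make_folds(meta[1:72, ], k = 10), "at least k")
})

test_that("tenfold CV is accurate on rhythmic data and near-random on shuffled labels", {
  coh <- generate_cohort(synth_config(n_individuals = 20, n_genes = 1000,
                                      rhythmic_fraction = 0.05, seed = 52))
  cv <- cv_tenfold(coh$expr, coh$meta, seed = 1, keep_models = TRUE)
  expect_lte(cv$summary$median_abs_error, 1.5)
  # every sample predicted exactly once, never by its own fold's model
  expect_setequal(cv$records$sample_id, coh$meta$sample_id)
  for (f in 1:10) {
    test_ids <- cv$records$sample_id[cv$records$fold == f]
    expect_length(intersect(test_ids, cv$models[[f]]$train_sample_ids), 0)
  }
  # summaries recompute from the records with no hidden state
  expect_equal(cv$summary$median_abs_error, median(cv$records$abs_error))
  expect_equal(cv$summary$circular_sd,
               circular_sd(cv$records$signed_error))

  shuffled <- coh$meta
  set.seed(99)
  shuffled$time <- sample(shuffled$time)
  cvs <- cv_tenfold(coh$expr, shuffled, seed = 1)
  expect_gt(cvs$summary$median_abs_error, 4.5)
})

test_that("identical seeds give identical CV records", {
  coh <- small_cohort(seed = 53, n_genes = 200)
  a <- cv_tenfold(coh$expr, coh$meta, k = 5, seed = 2)
  b <- cv_tenfold(coh$expr, coh$meta, k = 5, seed = 2)
  expect_identical(a$records, b$records)
})

test_that("the parameter sweep reports one summary row per parameter pair", {
  coh <- small_cohort(seed = 54, n_individuals = 8,
                      samples_per_individual = 6, n_genes = 200)
  grid <- cv_sweep(coh$expr, coh$meta, sumabsv_grid = c(1, 2),
                   nSPC_grid = c(1, 2), k = 4, seed = 1)
  expect_equal(nrow(grid), 4)
  expect_setequal(names(grid), c("sumabsv", "nSPC", "median_abs_error",
                                 "iqr_abs_error", "circular_sd"))
  expect_true(all(is.finite(grid$median_abs_error)))
})

test_that("leave-one-study-out recovers an injected phase shift and a null gives none", {
  cfg <- synth_config(n_individuals = 18, n_genes = 1000,
                      rhythmic_fraction = 0.05, noise_sd = 0.5,
                      individual_phase_sd = 0.5,
                      perturbation = list(condition = "perturbation",
                                          phase_shift = 2,
                                          noise_multiplier = 1,
                                          frac_individuals = 0.5),
                      seed = 55)
  coh <- generate_cohort(cfg)
  r <- cv_leave_one_study_out(coh$expr, coh$meta)
  cc <- r$conditions
  contrast <- merge(cc[cc$condition == "perturbation", ],
                    cc[cc$condition == "control", ], by = "study_id")
  expect_equal(mean(contrast$phase_delay.x - contrast$phase_delay.y), 2,
               tolerance = 0.75)

  null_cfg <- synth_config(n_individuals = 18, n_genes = 1000,
                           rhythmic_fraction = 0.05, noise_sd = 0.5,
                           individual_phase_sd = 0.5, seed = 55)
  null_coh <- generate_cohort(null_cfg)
  rn <- cv_leave_one_study_out(null_coh$expr, null_coh$meta)
  expect_true(all(abs(rn$conditions$phase_delay) < 1.2))
  expect_error(
    cv_leave_one_study_out(coh$expr,
                           transform(coh$meta, study_id = "study1")),
    "at least 2")
})

test_that("a noisier perturbation inflates the circular SD of its errors", {
  cfg <- synth_config(n_individuals = 18, n_genes = 1000,
                      rhythmic_fraction = 0.05, noise_sd = 0.5,
                      individual_phase_sd = 0.5,
                      perturbation = list(condition = "perturbation",
                                          phase_shift = 0,
                                          noise_multiplier = 4,
                                          frac_individuals = 0.5),
                      seed = 56)
  coh <- generate_cohort(cfg)
  r <- cv_leave_one_study_out(coh$expr, coh$meta)
  cc <- r$conditions
  sd_p <- cc$circular_sd[cc$condition == "perturbation"]
  sd_c <- cc$circular_sd[cc$condition == "control"]
  expect_gt(mean(sd_p), mean(sd_c))
})

test_that("the spline-peak estimator sees an injected shift as an advance of gene peaks", {
  cfg <- synth_config(n_individuals = 12, samples_per_individual = 10,
                      n_genes = 300, rhythmic_fraction = 0.2,
                      noise_sd = 0.3, individual_phase_sd = 0,
                      perturbation = list(condition = "perturbation",
                                          phase_shift = 2,
                                          noise_multiplier = 1,
                                          frac_individuals = 0.5),
                      seed = 57)
  coh <- generate_cohort(cfg)
  g <- coh$truth$genes
  strong <- g$gene_id[g$rhythmic][order(-g$amplitude[g$rhythmic])][1:10]
  shift <- phase_shift_by_splines(coh$expr, coh$meta, strong,
                                  "perturbation", "control")
  # rhythmic components evaluated at t + 2 h peak 2 h earlier in clock time
  expect_equal(shift, -2, tolerance = 0.75)
})

test_that("personal LOO cross-validation isolates folds and aligns paired outputs", {
  coh <- small_cohort(seed = 58, n_individuals = 10, n_genes = 300,
                      rhythmic_fraction = 0.1)
  r <- cv_personal_loo(coh$expr, coh$meta, k = 5, seed = 1)
  expect_setequal(r$records$sample_id, coh$meta$sample_id)
  expect_equal(anyDuplicated(r$records$sample_id), 0)
  expect_true(all(c("universal", "personal", "ensemble") %in%
                    names(r$records)))
  expect_setequal(r$summary$predictor, c("universal", "personal", "ensemble"))
  # ensemble is the circular mean of the paired member predictions
  expect_equal(r$records$ensemble,
               mapply(function(u, p) circular_mean(c(u, p)),
                      r$records$universal, r$records$personal),
               tolerance = 1e-12)
})

test_that("per-individual ensembles beat the universal predictor for most individuals", {
  coh <- small_cohort(seed = 59, n_individuals = 10, n_genes = 500,
                      rhythmic_fraction = 0.05, individual_phase_sd = 1.5)
  r <- cv_personal_loo(coh$expr, coh$meta, k = 5, seed = 1)
  per_ind <- aggregate(cbind(universal_abs_error, ensemble_abs_error) ~
                         individual_id, data = r$records, FUN = median)
  frac <- mean(per_ind$ensemble_abs_error < per_ind$universal_abs_error)
  expect_gt(frac, 0.5)
})
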