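test_that("training is deterministic: identical input, identical serialized model", {
  coh <- small_cohort(seed = 2)
  f1 <- circatime(coh$expr, coh$meta)
  f2 <- circatime(coh$expr, coh$meta)
  p1 <- tempfile(); p2 <- tempfile()
  write_model(f1, p1); write_model(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the two components peak roughly a quarter period apart", {
  coh <- generate_cohort(synth_config(n_individuals = 20, n_genes = 1000,
                                      rhythmic_fraction = 0.1, seed = 3))
  fit <- circatime(coh$expr, coh$meta)
  peaks <- vapply(fit$spc_splines, peak_time, numeric(1))
  gap <- circular_error(peaks[1], peaks[2])$absolute_error
  expect_gt(gap, 3)   # hours
  expect_lt(gap, 9)
})

test_that("a single dominant rhythmic gene captures the first component", {
  coh <- small_cohort(seed = 8, n_genes = 200, rhythmic_fraction = 0.05,
                      noise_sd = 0.5)
  dom <- rownames(coh$expr)[1]
  boosted <- coh$expr
  # huge amplitude at tiny noise: far higher SNR than any other gene
  set.seed(1)
  boosted[dom, ] <- 8 * cos(2 * pi * coh$meta$time) +
    rnorm(ncol(boosted), 0, 0.1)
  fit <- circatime(boosted, coh$meta, nSPC = 1)
  expect_gt(abs(coef(fit)[dom, 1]), 0.9)
})

test_that("log-likelihood is maximized on the spline means and matches a hand computation", {
  coh <- small_cohort(seed = 4)
  fit <- circatime(coh$expr, coh$meta)
  t0 <- 0.37
  z0 <- vapply(fit$spc_splines, function(s) predict(s, t0), numeric(1))
  grid <- (0:143) / 144
  ll <- log_likelihood(fit, z0, grid)
  expect_true(all(log_likelihood(fit, z0, t0) >= ll))
  # independent sum of normal log-densities at 13 points
  t13 <- (0:12) / 13
  set.seed(44)
  z <- z0 + rnorm(2)
  by_hand <- vapply(t13, function(t) {
    sum(vapply(1:2, function(k)
      dnorm(z[k], predict(fit$spc_splines[[k]], t), fit$spc_sd[k],
            log = TRUE), numeric(1)))
  }, numeric(1))
  expect_equal(log_likelihood(fit, z, t13), by_hand, tolerance = 1e-12)
  # inflating all SDs preserves the argmax
  fit2 <- fit
  fit2$spc_sd <- fit$spc_sd * 2
  p1 <- predict_from_scores_public(fit, z)
  p2 <- predict_from_scores_public(fit2, z)
  expect_equal(p1, p2, tolerance = 2 / fit$config$grid_size)
})

test_that("noiseless samples from the model are predicted at their generating time", {
  coh <- small_cohort(seed = 5)
  fit <- circatime(coh$expr, coh$meta)
  times <- c(0.05, 0.3, 0.62, 0.9)
  X <- simulate(fit, nsim = 1, seed = 1, times = times, noise_sd_scale = 0)
  pred <- unname(predict(fit, X))
  err <- circular_error(pred, times)$absolute_error
  expect_true(all(err < 0.01 * 24))
})

test_that("the likelihood argmax agrees with an exhaustive grid search", {
  coh <- small_cohort(seed = 7)
  fit <- circatime(coh$expr, coh$meta)
  grid <- (0:99999) / 1e5
  for (j in 1:4) {
    x <- coh$expr[, j]
    names(x) <- rownames(coh$expr)
    z <- drop(project_spcs(x, fit$spc_model))
    brute <- grid[which.max(log_likelihood(fit, z, grid))]
    t_hat <- unname(predict(fit, x))
    d <- abs(t_hat - brute)
    expect_lt(min(d, 1 - d), 1 / 1440)
  }
})

test_that("training commutes with rotation of the observed times", {
  coh <- small_cohort(seed = 9, n_individuals = 10, n_genes = 300)
  fit <- circatime(coh$expr, coh$meta)
  x <- coh$expr[, 5]
  names(x) <- rownames(coh$expr)
  # a knot-spacing shift maps the spline space onto itself: near-exact
  meta3 <- coh$meta
  meta3$time <- wrap_time(meta3$time + 1 / 3)
  fit3 <- circatime(coh$expr, meta3)
  expect_equal(unname(predict(fit3, x)),
               wrap_time(unname(predict(fit, x)) + 1 / 3), tolerance = 1e-4)
  # a generic shift holds approximately
  meta4 <- coh$meta
  meta4$time <- wrap_time(meta4$time + 0.25)
  fit4 <- circatime(coh$expr, meta4)
  d <- abs(unname(predict(fit4, x)) - wrap_time(unname(predict(fit, x)) + 0.25))
  expect_lt(min(d, 1 - d), 0.03)
})

test_that("predictions are invariant to gene order and duplicated background genes", {
  coh <- small_cohort(seed = 10, n_genes = 200)
  fit <- circatime(coh$expr, coh$meta)
  x <- coh$expr[, 3]
  names(x) <- rownames(coh$expr)
  base <- unname(predict(fit, x))

  perm <- sample(nrow(coh$expr))
  fitp <- circatime(coh$expr[perm, ], coh$meta)
  expect_equal(sort(predictor_genes(fitp)), sort(predictor_genes(fit)))
  expect_equal(unname(predict(fitp, x)), base, tolerance = 1e-6)

  background <- setdiff(rownames(coh$expr), predictor_genes(fit))[1]
  dup <- rbind(coh$expr, dup_gene = coh$expr[background, ])
  fitd <- circatime(dup, coh$meta)
  xd <- c(x, dup_gene = unname(x[background]))
  expect_equal(unname(predict(fitd, xd)), base, tolerance = 1e-5)
})

test_that("cross-validated error shrinks as synthetic noise shrinks", {
  meds <- vapply(c(0.5, 1.5, 4), function(sd) {
    coh <- small_cohort(seed = 12, n_individuals = 8,
                        samples_per_individual = 6, n_genes = 300,
                        noise_sd = sd)
    cv_tenfold(coh$expr, coh$meta, k = 4, seed = 1)$summary$median_abs_error
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("restricting features to low-SNR genes degrades accuracy", {
  coh <- small_cohort(seed = 14, n_individuals = 10, n_genes = 400,
                      rhythmic_fraction = 0.1)
  g <- coh$truth$genes
  rhythmic <- g[g$rhythmic, ]
  weak <- rhythmic$gene_id[order(rhythmic$amplitude)][1:10]
  full <- cv_tenfold(coh$expr, coh$meta, k = 5, seed = 1)
  weak_cv <- cv_tenfold(coh$expr[weak, ], coh$meta, k = 5, seed = 1)
  expect_gt(weak_cv$summary$median_abs_error, full$summary$median_abs_error)
})

test_that("zero-variance genes are dropped with a message and recorded", {
  coh <- small_cohort(seed = 15, n_genes = 100)
  expr <- rbind(coh$expr, flat = rep(1, ncol(coh$expr)))
  expect_message(fit <- circatime(expr, coh$meta), "zero-variance")
  expect_identical(fit$dropped_genes, "flat")
  expect_false("flat" %in% predictor_genes(fit))
})

test_that("degenerate training inputs error clearly", {
  coh <- small_cohort(seed = 16, n_genes = 50)
  meta1 <- coh$meta
  meta1$time <- rep(0.25, nrow(meta1))
  expect_error(circatime(coh$expr, meta1), "degenerate time coverage")
  expect_error(circatime(unname(coh$expr), coh$meta), "names")
  x <- coh$expr[, 1]
  names(x) <- rownames(coh$expr)
  fit <- circatime(coh$expr, coh$meta)
  expect_error(predict(fit, x[setdiff(names(x), predictor_genes(fit)[1])]),
               "missing")
})

test_that("model files round-trip predictions to machine accuracy, byte-stably", {
  coh <- small_cohort(seed = 17)
  fit <- circatime(coh$expr, coh$meta)
  path <- tempfile(fileext = ".json")
  write_model(fit, path)
  restored <- read_model(path)
  X <- coh$expr[, 1:6]
  expect_equal(unname(predict(restored, X)), unname(predict(fit, X)),
               tolerance = 1e-12)
  path2 <- tempfile()
  write_model(restored, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("summary, plot, fitted and residuals methods work", {
  coh <- small_cohort(seed = 18, n_individuals = 8,
                      samples_per_individual = 6, n_genes = 150)
  fit <- circatime(coh$expr, coh$meta)
  s <- summary(fit)
  expect_s3_class(s, "summary.circatime")
  expect_equal(nrow(s$components), 2)
  expect_output(print(fit), "Circadian time predictor")
  grDevices::pdf(NULL)
  expect_silent(plot(fit, pch = 20))
  grDevices::dev.off()
  f <- fitted(fit)
  expect_length(f, ncol(coh$expr))
  r <- residuals(fit)
  expect_true(all(abs(r) <= 12))
  expect_equal(unname(r),
               circular_error(unname(f), coh$meta$time)$signed_error)
})
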