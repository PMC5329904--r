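# Shared fixture builders: small seeded cohorts generated in code.

small_cohort <- function(seed = 1, n_individuals = 12,
                         samples_per_individual = 8, n_genes = 400,
                         rhythmic_fraction = 0.05, noise_sd = 1,
                         individual_phase_sd = 1.5, ...) {
  generate_cohort(synth_config(
    n_individuals = n_individuals,
    samples_per_individual = samples_per_individual,
    n_genes = n_genes, rhythmic_fraction = rhythmic_fraction,
    noise_sd = noise_sd, individual_phase_sd = individual_phase_sd,
    seed = seed, ...))
}

# Lift component scores to a gene-space sample whose projection equals them,
# so prediction tests can run through the exported predict() surface.
predict_from_scores_public <- function(fit, z) {
  x <- drop(fit$spc_model$loadings %*%
              solve(crossprod(fit$spc_model$loadings), z))
  names(x) <- fit$spc_model$gene_ids
  unname(predict(fit, x))
}

# A hand-built single-component predictor whose score spline follows
# amp * cos(2*pi*(t - phase)) on one gene, with residual SD `sd`.
toy_predictor <- function(phase = 0, amp = 4, sd = 0.5, gene = "g1",
                          grid_size = 1440) {
  tt <- (0:47) / 48
  # 8 knots so the cosine (and hence the peak location) is represented
  # accurately at any phase; 3 knots would bias off-knot peaks by ~0.02
  fit <- fit_periodic_spline(tt, amp * cos(2 * pi * (tt - phase)),
                             n_knots = 8)
  model <- structure(list(loadings = matrix(1, 1, 1,
                                            dimnames = list(gene, "SPC1")),
                          gene_ids = gene, singular_values = 1,
                          sumabsv = 1, nSPC = 1),
                     class = "spc_model")
  structure(list(spc_model = model, spc_splines = list(fit), spc_sd = sd,
                 config = list(sumabsv = 1, nSPC = 1, n_knots = 3,
                               n_time = 12, grid_size = grid_size,
                               sd_floor = 1e-6),
                 dropped_genes = character(0), train_times = tt,
                 train_scores = NULL, train_sample_ids = NULL,
                 n_samples = length(tt), call = NULL),
            class = "circatime")
}
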