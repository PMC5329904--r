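# Seeded generator of multi-individual, multi-study rhythmic expression
# cohorts with the statistical structure the predictor assumes: a minority of
# genes rhythmic with heterogeneous amplitude and waveform, per-individual
# phase offsets, per-study batch shifts, and i.i.d. Gaussian noise on a log
# expression scale.

#' Configuration of a synthetic circadian cohort
#'
#' Defaults emulate a merged multi-study blood-transcriptome cohort: 60
#' individuals sampled 8 times each at 3-h intervals across 3 studies,
#' 10,000 genes of which 2% are rhythmic. Rhythmic amplitudes
#' (peak-to-trough, log-expression units) are log-uniform on
#' `amplitude_range`; with the default range `[1.5, 6]` and unit noise SD the
#' signal-to-noise ratio (range/RMSE) is centred near 3. Waveforms are a mix
#' of sinusoids and concentrated von-Mises-shaped bumps (rhythms need not be
#' sinusoidal). Each individual's clock is offset from external time by a
#' wrapped-normal draw with SD `individual_phase_sd` hours, and each gene
#' picks up an additive per-study batch shift.
#'
#' @param n_individuals Number of individuals (default 60).
#' @param samples_per_individual Samples per individual (default 8).
#' @param sampling_interval Hours between an individual's consecutive
#'   samples (default 3).
#' @param n_genes Number of genes (default 10000).
#' @param rhythmic_fraction Fraction of genes that are rhythmic (default
#'   0.02).
#' @param amplitude_range Peak-to-trough amplitude range, log-expression
#'   units (default `c(1.5, 6)`).
#' @param noise_sd Observation noise SD (default 1).
#' @param waveform_mix Proportions of sinusoid and bump waveforms (default
#'   `c(sinusoid = 0.8, bump = 0.2)`).
#' @param individual_phase_sd SD of per-individual phase offsets in hours
#'   (default 1.5; set 0 for a null cohort with no inter-individual phase
#'   variation).
#' @param n_studies Number of studies (default 3).
#' @param study_batch_sd SD of per-gene, per-study additive batch shifts
#'   (default 0.2).
#' @param perturbation Optional list describing a perturbed condition:
#'   `condition` (label), `phase_shift` (hours), `noise_multiplier`, and
#'   `frac_individuals` (fraction of each study's individuals perturbed,
#'   default 0.5).
#' @param bump_kappa Concentration of the bump waveform (default 8).
#' @param period Period in hours (default 24).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_individuals = 60, samples_per_individual = 8,
                         sampling_interval = 3, n_genes = 10000,
                         rhythmic_fraction = 0.02,
                         amplitude_range = c(1.5, 6), noise_sd = 1,
                         waveform_mix = c(sinusoid = 0.8, bump = 0.2),
                         individual_phase_sd = 1.5, n_studies = 3,
                         study_batch_sd = 0.2, perturbation = NULL,
                         bump_kappa = 8, period = 24, seed = 1) {
  cfg <- list(n_individuals = n_individuals,
              samples_per_individual = samples_per_individual,
              sampling_interval = sampling_interval, n_genes = n_genes,
              rhythmic_fraction = rhythmic_fraction,
              amplitude_range = amplitude_range, noise_sd = noise_sd,
              waveform_mix = waveform_mix,
              individual_phase_sd = individual_phase_sd,
              n_studies = n_studies, study_batch_sd = study_batch_sd,
              perturbation = perturbation, bump_kappa = bump_kappa,
              period = period, seed = seed)
  stopifnot(n_individuals >= 1, samples_per_individual >= 1, n_genes >= 1,
            rhythmic_fraction > 0, rhythmic_fraction < 1,
            length(amplitude_range) == 2,
            amplitude_range[1] > 0, diff(amplitude_range) >= 0,
            noise_sd >= 0, n_studies >= 1, study_batch_sd >= 0, period > 0)
  if (!is.null(perturbation)) {
    defaults <- list(condition = "perturbation", phase_shift = 0,
                     noise_multiplier = 1, frac_individuals = 0.5)
    cfg$perturbation <- utils::modifyList(defaults, perturbation)
  }
  structure(cfg, class = "synth_config")
}

# Unit peak-to-trough waveform value at scaled time t for phase `phase`
# (peak at t = phase). Range is [-1/2, 1/2].
waveform_value <- function(t, phase, waveform, kappa) {
  u <- 2 * pi * (t - phase)
  if (waveform == "sinusoid") return(0.5 * cos(u))
  raw <- exp(kappa * (cos(u) - 1))
  lo <- exp(-2 * kappa)
  (raw - lo) / (1 - lo) - 0.5
}

#' Reconstruct noiseless expression from a cohort's truth tables
#'
#' The generator's truth tables (gene parameters, individual offsets, batch
#' shifts, configuration) fully determine the noiseless expression; this
#' rebuilds it for any subset of metadata rows, e.g. to separate signal from
#' noise in a generated cohort.
#'
#' @param truth The `truth` component of a `ct_cohort`.
#' @param meta Metadata rows (any subset of the cohort's `meta`).
#' @return Genes-by-samples matrix of noiseless expression.
#' @export
cohort_noiseless <- function(truth, meta) {
  genes <- truth$genes
  inds <- truth$individuals
  cfg <- truth$config
  offset_h <- stats::setNames(inds$phase_offset_h, inds$individual_id)
  study_of <- stats::setNames(inds$study_id, inds$individual_id)
  ind <- as.character(meta$individual_id)
  t_int <- meta$time - offset_h[ind] / cfg$period
  shift <- if (!is.null(meta$condition) && !is.null(cfg$perturbation))
    ifelse(meta$condition == cfg$perturbation$condition,
           cfg$perturbation$phase_shift / cfg$period, 0)
  else rep(0, nrow(meta))
  t_eval <- t_int + shift
  M <- matrix(rep(genes$baseline, nrow(meta)), nrow = nrow(genes)) +
    truth$batch[, study_of[ind], drop = FALSE]
  for (i in which(genes$rhythmic)) {
    M[i, ] <- M[i, ] + genes$amplitude[i] *
      waveform_value(t_eval, genes$phase[i], genes$waveform[i],
                     cfg$bump_kappa)
  }
  dimnames(M) <- list(genes$gene_id, as.character(meta$sample_id))
  M
}

#' Generate a synthetic circadian cohort
#'
#' Draws a full cohort from a [synth_config()]: sample times on a per-
#' individual schedule (random start, fixed interval), gene truth (rhythmic
#' flag, baseline, amplitude, phase, waveform), per-individual phase offsets,
#' per-study batch shifts, and Gaussian observation noise. The truth tables
#' are sufficient to reconstruct the noiseless expression exactly. If the
#' configuration carries a `perturbation`, the stated fraction of each
#' study's individuals is relabelled to the perturbed condition, their
#' rhythmic components evaluated at `t + phase_shift` and their noise scaled.
#'
#' @param config A `synth_config`.
#' @return A list of class `ct_cohort`: `expr` (genes by samples), `meta`
#'   (`sample_id`, `individual_id`, `study_id`, `condition`, `time` scaled to
#'   `[0, 1)`, `time_hours`), and `truth` (`genes`, `individuals`, `batch`,
#'   `noise`, `config`).
#' @examples
#' coh <- generate_cohort(synth_config(n_individuals = 6, n_genes = 50,
#'                                     rhythmic_fraction = 0.2, seed = 7))
#' dim(coh$expr)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n_ind <- cfg$n_individuals
    spi <- cfg$samples_per_individual
    ind_ids <- sprintf("I%03d", seq_len(n_ind))
    study_ids <- sprintf("study%d", rep_len(seq_len(cfg$n_studies), n_ind))
    offsets <- stats::rnorm(n_ind, 0, cfg$individual_phase_sd)

    condition <- rep("control", n_ind)
    if (!is.null(cfg$perturbation)) {
      for (s in unique(study_ids)) {
        members <- which(study_ids == s)
        n_pert <- round(length(members) * cfg$perturbation$frac_individuals)
        if (n_pert > 0)
          condition[sample(members, n_pert)] <- cfg$perturbation$condition
      }
    }
    individuals <- data.frame(individual_id = ind_ids, study_id = study_ids,
                              phase_offset_h = offsets,
                              condition = condition,
                              stringsAsFactors = FALSE)

    starts <- stats::runif(n_ind, 0, cfg$sampling_interval)
    meta <- do.call(rbind, lapply(seq_len(n_ind), function(u) {
      hours <- wrap_time(starts[u] + cfg$sampling_interval * (seq_len(spi) - 1),
                         cfg$period)
      data.frame(sample_id = sprintf("%s_S%02d", ind_ids[u], seq_len(spi)),
                 individual_id = ind_ids[u], study_id = study_ids[u],
                 condition = condition[u], time = hours / cfg$period,
                 time_hours = hours, stringsAsFactors = FALSE)
    }))

    n_genes <- cfg$n_genes
    n_rhythmic <- max(1, round(n_genes * cfg$rhythmic_fraction))
    rhythmic <- rep(FALSE, n_genes)
    rhythmic[sample.int(n_genes, n_rhythmic)] <- TRUE
    waveforms <- sample(names(cfg$waveform_mix), n_genes, replace = TRUE,
                        prob = cfg$waveform_mix)
    genes <- data.frame(
      gene_id = sprintf("G%05d", seq_len(n_genes)),
      rhythmic = rhythmic,
      baseline = stats::rnorm(n_genes, 7, 2),
      amplitude = ifelse(rhythmic,
                         exp(stats::runif(n_genes, log(cfg$amplitude_range[1]),
                                          log(cfg$amplitude_range[2]))), 0),
      phase = stats::runif(n_genes),
      waveform = ifelse(rhythmic, waveforms, NA_character_),
      stringsAsFactors = FALSE)

    batch <- matrix(stats::rnorm(n_genes * cfg$n_studies, 0,
                                 cfg$study_batch_sd),
                    n_genes, cfg$n_studies,
                    dimnames = list(genes$gene_id,
                                    sprintf("study%d",
                                            seq_len(cfg$n_studies))))

    truth <- list(genes = genes, individuals = individuals, batch = batch,
                  config = cfg)
    noiseless <- cohort_noiseless(truth, meta)
    noise_scale <- rep(cfg$noise_sd, nrow(meta))
    if (!is.null(cfg$perturbation))
      noise_scale <- ifelse(meta$condition == cfg$perturbation$condition,
                            cfg$noise_sd * cfg$perturbation$noise_multiplier,
                            cfg$noise_sd)
    noise <- matrix(stats::rnorm(length(noiseless)), nrow(noiseless)) *
      rep(noise_scale, each = nrow(noiseless))
    expr <- noiseless + noise
    structure(list(expr = expr, meta = meta, truth = truth),
              class = "ct_cohort")
  })
}

#' @export
print.ct_cohort <- function(x, ...) {
  cat("Synthetic circadian cohort:", nrow(x$expr), "genes x", ncol(x$expr),
      "samples;", sum(x$truth$genes$rhythmic), "rhythmic genes,",
      nrow(x$truth$individuals), "individuals,",
      length(unique(x$truth$individuals$study_id)), "studies\n")
  invisible(x)
}

#' Inject a phase-shift/noise perturbation into cohort samples
#'
#' Rebuilds the named samples with their rhythmic components evaluated at
#' `t + phase_shift` and their original noise scaled by `noise_multiplier`,
#' relabelling them with the perturbed condition. With `phase_shift = 0` and
#' `noise_multiplier = 1` the expression is unchanged. The same noise draws
#' are reused, so the perturbation is the only difference.
#'
#' @param cohort A `ct_cohort` from [generate_cohort()].
#' @param sample_ids Samples to perturb.
#' @param phase_shift Phase shift in hours.
#' @param noise_multiplier Noise scale factor (default 1).
#' @param condition New condition label (default `"perturbation"`).
#' @return The modified `ct_cohort`.
#' @export
inject_perturbation <- function(cohort, sample_ids, phase_shift,
                                noise_multiplier = 1,
                                condition = "perturbation") {
  stopifnot(inherits(cohort, "ct_cohort"))
  if (!all(sample_ids %in% cohort$meta$sample_id))
    stop_ct("unknown sample id(s)")
  noise <- cohort$expr - cohort_noiseless(cohort$truth, cohort$meta)
  rows <- cohort$meta$sample_id %in% sample_ids
  meta2 <- cohort$meta
  meta2$condition[rows] <- condition
  cfg <- cohort$truth$config
  cfg$perturbation <- list(condition = condition, phase_shift = phase_shift,
                           noise_multiplier = noise_multiplier,
                           frac_individuals = NA)
  truth2 <- cohort$truth
  truth2$config <- cfg
  noiseless2 <- cohort_noiseless(truth2, meta2[rows, , drop = FALSE])
  cohort$expr[, rows] <- noiseless2 +
    noise[, rows, drop = FALSE] * noise_multiplier
  cohort$meta <- meta2
  cohort$truth <- truth2
  cohort
}
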