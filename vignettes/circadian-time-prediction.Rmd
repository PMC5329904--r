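---
title: "Predicting circadian time from gene expression: model and methods"
author: "circatime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting circadian time from gene expression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circatime)
```

## The problem

Peripheral tissues such as blood express thousands of transcripts under
circadian control. Given a cohort in which each expression profile carries
an observed time of day, we want a predictor that reads the *circadian
time* (CT) of a new profile — ideally from very few genes, since a clinical
assay cannot measure a whole transcriptome. Throughout, time lives on the
unit circle: `t in [0, 1)` is the observed time divided by the 24-h period.
Hours appear only at input and reporting boundaries. All error statistics
are circular: the signed error between two times is the shorter arc
(within ±12 h), an exact 12-h tie is reported as +12 h, and a uniform
random predictor has expected absolute error of 6 h — the reference point
for every accuracy claim below.

## Training model

Training (`circatime()`) has four stages.

**1. Per-gene periodic splines.** Each gene's expression is regressed on
time using a cyclic cubic regression spline — continuous through the
period boundary up to second derivatives — with 3 equispaced knots at
`{0, 1/3, 2/3}`, fit by unpenalized least squares. Three knots give three
degrees of freedom per gene: enough for one asymmetric hump per cycle,
deliberately too few to chase noise. Because the basis is this small, an
explicit roughness penalty would have nothing left to do, which is why a
regression spline replaces a penalized smoothing spline here; the fitting
routine accepts any knot count, so a penalized variant could be swapped in
behind the same interface. The basis itself comes from mgcv
(`smoothCon(s(t, bs = "cc"))`); with all genes sharing one set of sample
times, the whole transcriptome is fit with a single QR decomposition.
The residual RMSE `s_j` (denominator `n`, taking "root mean squared
error" literally) doubles as the gene's noise scale.

**2. Discretization and scaling.** Each fitted curve is evaluated at 12
equispaced times, centred, and divided by `max(s_j, 1e-6)`. This is the
single most consequential inferred choice in the package: the scaling makes
a gene's magnitude in the decomposed matrix proportional to its
signal-to-noise ratio `SNR_j = (max f_j - min f_j) / s_j`, so the component
selection in stage 3 favours high-SNR genes. The floor handles noiseless
(e.g. simulated) genes.

**3. Sparse principal components.** The 12 × genes scaled matrix is
decomposed by rank-one penalized matrix decomposition: alternating updates
`u <- Xv/||Xv||` and `v <- S(X'u, delta)/||S(X'u, delta)||`, where the
soft-threshold `delta` is the smallest value (found by bisection, 80
halvings) bringing `||v||_1` within the budget `sumabsv`. `v` is
initialized at the leading right singular vector, making the procedure
deterministic without seeds; the sign convention (largest-magnitude
loading positive) makes serialized models reproducible byte for byte.
Components after the first are extracted from the deflated matrix
`X - d u v'`; they are not forced orthogonal, and the `d` sequence is not
guaranteed monotone. At `sumabsv = 1` the feasible set collapses to signed
unit basis vectors (one gene per component); at `sumabsv >= sqrt(n_genes)`
the constraint is vacuous and the result equals the leading singular
triplet — both limits are tested against closed form and dense `svd()`.

**4. Component splines.** Only genes with a nonzero loading are kept (the
predictor's signature — typically 10–15 genes at the defaults). Training
samples are projected (`z_k = v_k' x`, raw log-scale expression, no
re-scaling at projection time), and each component's scores get their own
3-knot periodic spline `g_k(t)` and residual SD `sigma_k`.

## Prediction likelihood

The distributional model is deliberately the simplest one consistent with
maximum-likelihood estimation on spline means: component scores are
independent Gaussians with time-dependent mean `g_k(t)` and time-*constant*
SD `sigma_k`,

```
L(t | x) = sum_k log N(v_k' x | g_k(t), sigma_k^2).
```

`sigma_k` is floored at 1e-6 so a perfect fit cannot produce an infinite
likelihood. A time-varying SD is a possible extension; nothing in the
interface precludes it. The argmax is located on a 1440-point grid (1-min
resolution on 24 h) and refined by local continuous optimization in the
winning cell; grid ties break toward the smallest time, so predictions are
deterministic. The same scan-and-refine routine backs `peak_time()` (phase
= argmax of a fitted curve, used when comparing conditions by clock-gene
peak shifts).

### Groups and ensembles

For a group of `n` samples from one individual taken known times apart
(`tau_i` relative to the reference sample, at least one `tau = 0`), the
group log-likelihood is `sum_i L((t + tau_i) mod 1 | x_i)` and the argmax
estimates the reference sample's time. All samples carry equal implicit
weight. Ensembles of predictors combine either by summing log-likelihood
profiles over a shared grid (a mismatched grid would silently bias the
argmax, so members must agree on `grid_size`) or by the circular mean of
the member predictions, `atan2(sum sin, sum cos)/2pi` — the simpler rule
and the default for universal+personal ensembles. A circular mean whose
resultant length falls below 1e-9 (antipodal members) raises an error
rather than returning an arbitrary direction that would silently corrupt
an ensemble. Weighted combination is deliberately not implemented.

### Personalization under universal guidance

Individuals differ in phase of entrainment, so a cohort-level ("universal")
predictor carries a per-individual bias. With only ~8 samples per
individual, training a personal predictor on the full transcriptome
overfits to uselessness — near-random cross-validated error, as the test
suite demonstrates on 2,000 synthetic genes. Universal guidance exploits
the universal predictor's feature selection: the personal training set is
restricted to the universal predictor's genes
(`shrink_training_set()`), and the standard pipeline runs on that tiny
matrix (`train_personal()`). The personal predictor may select a further
subset of the guiding genes. Training demands at least 4 samples at 3
distinct times (the mathematical floor) and warns below 7, where accuracy
is not expected to be robust. Personal `sumabsv`/`nSPC` default to the
universal values; personal `sigma_k` is *not* shrunk toward the universal
value despite the tiny n — a noted limitation. The final estimate is the
circular mean of the universal and personal predictions.

## Cross-validation harnesses

All schemes assign *individuals*, never samples, to folds (seeded shuffle,
round-robin deal), because within-individual correlation would otherwise
leak across the train/test boundary. `cv_tenfold()` is the main harness;
`cv_group_tenfold()` additionally predicts within-fold sample groups
(group structure is used only at test time); `cv_personal_loo()` runs
leave-one-sample-out per individual with the guiding universal predictor
trained without that individual's fold, and returns paired
universal/personal/ensemble predictions per held-out sample;
`cv_leave_one_study_out()` trains on the control samples of all but one
study and predicts everything in the held-out study. Summaries (median
absolute error, IQR, circular SD `period/2pi * sqrt(-2 log Rbar)`) are
recomputed from the per-sample records with no hidden state.

A condition's **apparent phase delay** is estimated as the circular mean of
its signed prediction errors. Because a held-out study contributes few
individuals, that raw delay also absorbs their mean phase offset; the
package therefore reports per-condition delays and leaves the
perturbation-minus-control contrast within each study as the meaningful
readout. A second estimator, `phase_shift_by_splines()`, compares
conditions by the circular mean of per-gene fitted peak shifts; note the
sign relation — a condition whose rhythmic program is evaluated at
`t + s` *predicts* `s` hours late but shows gene peaks `s` hours *earlier*.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the structure the method assumes,
and is the basis of every quantitative claim in the test suite. Defaults
emulate a merged multi-study blood cohort: 60 individuals × 8 samples at
3-h intervals (480 samples), 3 studies, 10,000 genes, 2% rhythmic.
Rhythmic gene `i` of individual `u` at time `t` is

```
baseline_i + A_i * w_i(t - phi_i - delta_u [+ shift]) + batch_{i,study(u)} + noise
```

with unit peak-to-trough waveform `w` (80% sinusoid, 20% von-Mises bump
with concentration 8 — rhythms need not be sinusoidal, and the bump is
exactly the kind of concentrated, asymmetric profile the spline must
tolerate), amplitude `A_i` log-uniform on [1.5, 6] log-units (geometric
mean 3, so SNR centres near 3 at the default unit noise SD), gene phase
`phi_i` uniform, individual offset `delta_u` normal with SD 1.5 h (0 for
null experiments), per-gene/study batch shift SD 0.2, and i.i.d. Gaussian
noise. A positive `delta_u` is a late clock: the individual's samples look
*earlier* than the wall clock to a universal predictor. The truth tables
reconstruct the noiseless matrix exactly (`cohort_noiseless()`), which is
what lets `inject_perturbation()` re-evaluate the rhythmic component at
`t + shift` and rescale the *same* noise draws, so a null injection is the
identity.

What the generator does *not* emulate: probe-level microarray artifacts,
count noise, missingness, non-stationary baselines (e.g. postprandial
responses), and realistic gene-gene correlation beyond the shared clock.
Passing tests therefore demonstrate correctness of the machinery and
sensible statistical behaviour under the stated model, not clinical-grade
accuracy on real cohorts.

## Numerical choices and problem sizes

- PMD: convergence when `max |v - v_old| < 1e-7`, at most 200 iterations
  (warn and return the best iterate otherwise); the objective trace is
  exposed and tested for monotone ascent.
- Argmax grids: 1440 points + local refinement for predictions and peak
  times; ties toward the smallest time.
- Rotation equivariance of training is exact for time shifts that are
  multiples of the knot spacing (the knot-anchored spline space maps onto
  itself) and approximate otherwise — a property of any fixed-knot basis.
- Degenerate inputs fail loudly: all-identical times, fewer observations
  than basis functions, constant profiles in `peak_time()`, antipodal
  circular means, missing predictor genes at projection.
- Model files are JSON at 17 significant digits, so doubles round-trip
  exactly and rewriting a restored model is byte-identical.
- Test and acceptance problem sizes: the full default cohort (10,000 ×
  480) for headline cross-validation; 2,000-gene cohorts of 20–40
  individuals for group, personalization, and perturbation experiments —
  sizes chosen so each experiment has adequate power for a
  median-vs-median comparison while a complete run stays in the minutes
  range on a single core.

## Known limitations

Constant-SD Gaussian likelihood (no heavy tails, no time-varying
dispersion); no prediction intervals; no covariate adjustment; no learned
ensemble weights; cross-study normalization is assumed done upstream (the
package consumes an already-merged matrix); personal predictors require
the universal genes to be measured in the personal samples.
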