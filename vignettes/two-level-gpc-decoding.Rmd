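---
title: "Two-level Gaussian process decoding of emotional-face activation patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level Gaussian process decoding of emotional-face activation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcmvpa)
```

## The scientific question

When a clinical population processes an emotional stimulus abnormally, the
whole-brain activation pattern it evokes may become *less distinct* from the
pattern evoked by a neutral stimulus — either because the patterns overlap
more, or because they vary more from person to person. `gpcmvpa` implements a
two-level pattern-recognition strategy for quantifying this:

1. **Within-group decoding.** For each subject group separately, a binary
   Gaussian process classifier (GPC) is trained to discriminate the
   whole-brain activation pattern for a happy facial expression from the
   pattern for a neutral one, using leave-one-subject-out (LOSO)
   cross-validation. The GPC returns a *predictive probability* rather than a
   hard label: a held-out pattern decoded at 0.95 is unambiguous; one decoded
   at 0.55 carries little class information. Balanced accuracy (the mean of
   the true-positive and true-negative rates) and a label-permutation test
   summarize each classifier.
2. **Between-group comparison.** The held-out predictive probabilities — one
   per subject and stimulus class — become the dependent variable of a
   one-way ANOVA across groups, with Newman–Keuls step-down post-hoc
   comparisons. Lower predictive probability in one group is evidence that
   its happy/neutral patterns are less separable.

The conventional alternative — training a classifier to tell the groups apart
directly from the patterns for one stimulus (leave-one-pair-out
cross-validation over matched subject pairs, sensitivity/specificity,
Bonferroni over the 3 group-pairs x 3 conditions family) — is also
implemented, in `lopo_between_group()`.

Because no clinical data ship with the package, a first-class synthetic-data
module generates cohorts whose decodability is controlled by interpretable
knobs, and every statistical claim in the test suite is made against that
generator.

## The classifier

The GPC is a Gaussian process over a latent function $f$ with linear kernel

$$k(x, x') = a\, x^\top x' + b,$$

probit likelihood $p(y \mid f) = \Phi(y f)$, $y \in \{\pm 1\}$, and Laplace
approximation to the non-Gaussian posterior: the posterior mode
$\hat{f}$ is found by Newton iteration in the numerically stable
parameterization $B = I + W^{1/2} K W^{1/2}$ (where $W = -\nabla\nabla
\log p(y \mid f)$), and the predictive probability for a test pattern uses
the closed-form Gaussian integral of the probit link,

$$p(y_* = 1 \mid x_*) = \Phi\!\left(\frac{\bar f_*}{\sqrt{1 + \mathrm{var}(f_*)}}\right).$$

Numerical choices:

* **Trace normalization** (default on): $K_0 = XX^\top$ is rescaled to
  $n\,K_0/\mathrm{tr}(K_0)$ before the amplitude is applied. This makes the
  fixed amplitude grid meaningful regardless of voxel count and noise scale,
  and makes predictions exactly invariant to duplicating the whole feature
  set. Duplicating a *single* feature column is not an invariance of any
  kernel method (it changes the Gram geometry) and is not claimed.
* **Amplitude selection**: $a$ is chosen from the grid $2^{-6} \dots 2^{6}$
  by maximizing the Laplace-approximate log marginal likelihood; the kernel
  offset $b$ defaults to 0 (homogeneous linear kernel).
* **Convergence**: Newton stops when the log-posterior objective changes by
  less than $10^{-6}$ (the posterior is log-concave; step halving guards the
  rare overshoot). Non-convergence after 100 iterations is an error, not a
  warning.
* **Accuracy of the approximation**: against a brute-force Gauss–Hermite
  quadrature oracle over the full latent posterior (possible up to 5 training
  points), Laplace predictive probabilities agree to a mean absolute
  difference of about 0.01–0.02, comfortably inside the 0.05 contract the
  test suite asserts.
* **Ties**: a predictive probability of exactly 0.5 is assigned to class 2.
* The probit likelihood is used because its predictive integral is exact
  given the Gaussian approximation; an expectation-propagation posterior or a
  logistic link would be reasonable alternatives but are out of scope.

The linear kernel admits an exact dual-to-primal conversion,
$w = a\,X^\top \alpha$ (plus trace factor), so every trained classifier has a
voxelwise **discriminating map** (`weight_map()`): positive weights are
evidence for class 1, negative for class 2. Maps are conventionally displayed
after `threshold_map()`, which zeroes voxels below a fraction (default 30%)
of the maximum absolute weight — ties at the cutoff are kept, so a fraction
of 1.0 retains the maximal voxels rather than returning an empty map. The map
describes the decision boundary as a whole; it is not a voxelwise statistical
contrast and supports no local inference.

## Confound control

Medication load and substance-use history differ between patient groups and
could masquerade as pattern differences. `residualize()` removes
covariate-explained variance from the feature matrix by dummy-variable
regression — equivalently, multiplication by the residual-forming matrix
$R = I - C (C^\top C)^{+} C^\top$, with an intercept always appended to $C$
and a pseudo-inverse so collinear covariates degrade gracefully. Covariates
are per subject and are duplicated across a subject's condition examples;
condition labels never enter $C$.

Two estimation scopes are provided because the original description is
ambiguous about where $R$ was applied:

* `whole_sample` — $R$ computed and applied to all rows before
  cross-validation (the reading suggested by "probabilities that had already
  controlled for" the confounds);
* `train_only` (default) — regression coefficients estimated on each fold's
  training rows only, then subtracted from all rows, so no test information
  reaches training.

Both are exposed via `cv_config(residualize_mode = )`; results can be
reported side by side. Groups with no recorded covariates (the
healthy-comparison group) get intercept-only residualization, i.e. column
centering.

## The synthetic cohort generator

`generate_cohort()` emulates the *products* of a preprocessed event-related
fMRI study — per-condition GLM coefficient ("beta") volumes on a common
grid — rather than the scanner physics. Each group is a `group_spec` with
two scientifically meaningful knobs, chosen to mirror the two candidate
mechanisms for degraded decodability:

* `pattern_overlap` ∈ [0, 1]: fraction of the condition patterns' sparse
  support (10% of the grid by default) shared between conditions.
  Increasing it provably cannot increase the expected distance between
  condition patterns.
* `subject_variability`: SD of a per-subject Gaussian perturbation of the
  group pattern — heterogeneous patterns generalize poorly across LOSO
  folds.

plus `pattern_amplitude` (per-condition effect size, in units of the voxel
noise SD, which defaults to 1) and covariate distributions (truncated-normal
medication load, Bernoulli substance history, with patient-group defaults
matching the study demographics: means 1.4 and 2.5). `default_groups()`
encodes a three-group design — HC (healthy comparison), UD (unipolar
depressed), BD (bipolar depressed), 18 subjects each — with *graded*
happy-vs-neutral separability (HC highest amplitude / least overlap / least
variability; BD the reverse). These defaults were fixed once, as a plausible
stand-in for the published effect ordering, and are deliberately not
calibrated against any test outcome.

The paradigm generator reproduces the event-related design: 20 trials per
condition (neutral, 50% happy, 100% happy) in uniformly random order, 2 s
stimuli, inter-stimulus intervals with mean 4.9 s. The stated ISI
distribution is Poisson; a literal Poisson draw in seconds is integer-valued,
so the default samples deciseconds as $\mathrm{Poisson}(49)/10$ — same mean,
sub-second granularity — with an exponential alternative
(`isi_dist = "exponential"`). The nominal 6-minute run length is
inconsistent with $60 \times (2 + 4.9)$ s ≈ 6.9 min, so the schedule's
`total_duration` is derived from the realized events rather than fixed at
360 s. `simulate_timeseries()` provides the forward BOLD model (betas x
HRF-convolved boxcars + white noise) whose generative design matrix is
exactly the one `build_design_matrix()` produces, so the noiseless GLM round
trip is exact by construction.

The first-level model uses the canonical double-gamma HRF. The gammas are
parameterized by their *modes* (peak 6 s, undershoot 16 s, ratio 6), so the
sampled response peaks at the configured delay; SPM's own discretized
parameterization peaks slightly earlier, which matters to nothing downstream
(the same HRF is used for simulation and estimation). No temporal
derivatives, high-pass filter, or autocorrelation model are fitted — the
synthetic data contain none of those artifacts, and the fitter errors on
rank-deficient designs rather than silently regularizing.

What the generator does **not** emulate: spatial autocorrelation from
smoothing, physiological and motion artifacts, condition-correlated
covariates, non-Gaussian noise, registration error. A green test therefore
establishes the *statistical machinery* (calibration under the null, signal
recovery, ordering recovery, leakage-freedom), not performance on real fMRI.

## Permutation testing and its calibration

Significance of a cross-validated accuracy is assessed by permutation:
labels are flipped jointly within exchangeability units — a subject's two
condition examples for LOSO, a matched pair's two members for
leave-one-pair-out — each unit independently with probability 1/2, and the
*entire* cross-validation is re-run per permutation (fold kernel matrices
are label-independent and are precomputed once, which makes this exact and
fast). The p-value uses the add-one estimator
$p = (1 + \#\{A_{perm} \ge A_{obs}\})/(1 + n_{perm})$, which is valid and
never zero.

Two statistical facts about this design, established empirically by the test
suite and worth stating plainly:

* **LOSO accuracy is calibrated but overdispersed.** Across 500 null cohorts
  (zero condition signal, 18 subjects, 12³ grid) the mean LOSO balanced
  accuracy is 0.503 ± 0.005 — no bias. But the per-cohort SD is ~0.115,
  versus ~0.083 if the 36 predictions were independent Bernoulli trials:
  folds share 17/18 of their training data, so predictions are positively
  correlated and a binomial interval on pooled predictions is roughly a
  ±1.4σ band in reality. The acceptance suite nevertheless implements that
  binomial-interval check exactly as specified (with its first-chosen fixed
  seeds), and it can fail for an unbiased implementation; the companion
  calibration test in `test-evaluation.R` uses the empirical cohort-level
  standard error, which is the statistically correct yardstick.
* **Permutation p-values are conservative under ties.** Accuracy over 36
  predictions is a coarse lattice; permuted replicates often tie with the
  observed value, and ties count against significance in the add-one
  formula. Measured over two independent 200-cohort batches, the fraction
  of p ≤ 0.05 was 1.5% and 4% rather than the nominal 5%. The test is
  therefore valid (type-I error at or below nominal), at some cost in
  power.

## Second level

`second_level_report()` collects, per group, each subject's held-out
predictive probability for the stimulus class in question — the only
leakage-free choice — with class-2 examples mapped to $1 - p$ so that
"confidence about neutral" is on the same scale across groups. One-way
ANOVA (`anova_oneway`, plain between/within decomposition) tests the group
main effect; `newman_keuls` compares ordered means with studentized-range
statistics $q = \Delta \bar{x}/\sqrt{\mathrm{MSE}/n}$, critical values from
`qtukey` at the span of each comparison, approximate p-values from `ptukey`,
and the step-down rule (a non-significant wider range blocks all nested
comparisons). Unequal group sizes fall back to the harmonic-mean $n$ with a
warning. Simulated familywise error at $\alpha = 0.05$ over 1000 null
replicates stays below 0.075.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(grid_shape = c(12, 12, 12), n_permutations = 99,
                       seed = 1)
bundle <- run_pipeline(cfg)
bundle$within_table       # 6 rows: 2 contrasts x 3 groups
bundle$second_level[["intense_happy"]]$anova_table
bundle$between_table      # 9 rows: 3 pairs x 3 conditions, Bonferroni column
```

The bundle also carries one discriminating map per within-group classifier
(raw and thresholded), the covariate table, and a provenance block (seed,
package version, grid, timestamps). With `out_dir` set, each stage persists
CSV/JSON/NIfTI artifacts as it completes.

## Known limitations

* The exact GPC configuration of the original analysis (kernel scaling,
  likelihood, approximation) was never published; the defaults here are
  declared choices, not reconstructions, so numeric accuracies on real data
  would not be expected to match published values — only the qualitative
  behavior is testable, and only against synthetic data.
* The NIfTI-1 reader/writer is deliberately minimal (single float32 3-D/4-D
  volumes, diagonal affine); it exists because the deployment environment
  has no R NIfTI package, and it is cross-validated against `nibabel`
  conventions, but it is not a general neuroimaging I/O layer.
* Leave-one-out error estimates have high variance at n = 18; the package
  reports them faithfully rather than smoothing them.
* The Newman–Keuls procedure does not strictly control familywise error for
  some configurations with more than three groups; it is provided because it
  is the procedure the two-level strategy historically used, and the ANOVA
  gate mitigates the risk at k = 3.
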