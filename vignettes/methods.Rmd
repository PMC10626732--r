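---
title: "Models and methods behind chemomethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemomethyl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemomethyl)
```

`chemomethyl` analyses treatment-associated DNA-methylation change on
microarray beta values (methylated / total signal, in [0, 1]). This
vignette explains each model, the assumptions it leans on, the parameters
that matter, and the design choices made where the methodology was
genuinely open. Every empirical statement here is one the package's test
suite or acceptance script computes itself.

## What the synthetic generator emulates — and what it does not

All validation runs on cohorts from `simulate_cohort()`, because the
motivating studies' patient data are not publicly deposited. The
generator emulates the statistical structure the analysis assumes:

* **Designs.** A paired arm (default 125 subjects, one pre- and one
  post-treatment blood sample each) and a single-time-point arm (default
  1,066 treated / 742 untreated for blood, 207/130 for saliva), with
  batch, age, ethnicity and diagnosis-year covariates on the sheet.
* **Cell mixtures.** Per sample a 7-type blood composition is drawn from
  a Dirichlet whose mean mirrors typical whole-blood medians
  (granulocyte-dominated, ~6% monocytes); saliva uses a 2-type
  leukocyte/epithelial reference. At each cell-type marker probe the
  latent beta is the reference profile mixed by the true fractions.
* **Background methylome.** Non-marker probes draw a trimodal baseline
  (unmethylated / hemimethylated / methylated modes weighted
  0.22/0.12/0.66), which puts the genome-wide mean near 0.655 and gives
  the three-state normalization model real structure to fit.
* **Treatment effects.** A configurable fraction of probes (default 2%)
  receives a signed beta-scale shift (default mean 0.10, drawn within
  ±25%), organised so that most causal probes fall in whole causal
  promoters — this is what makes promoter aggregation and gene-set
  enrichment recoverable. Treated samples see the shift scaled by
  `2^(-t/h)` with `t` years since treatment start and `h` the planted
  half-life (default 1 year). The shift magnitude is an assumption, not a
  calibrated value: the source studies do not report the distribution of
  chemotherapy-induced beta shifts.
* **Technical structure.** 30% type-I / 70% type-II probes, with type-II
  betas compressed toward 0.5 on the logit scale (divisor 1.4) so BMIQ
  has a realistic distortion to undo; per-batch and (paired-arm)
  per-subject scalar offsets; observation noise
  `Beta(mu*nu, (1-mu)*nu)` with concentration `nu = 100`, which respects
  the [0, 1] support and gives an SD near 0.047 at mu = 0.5 — array-like
  precision; a small fraction of unreliable probes with elevated
  detection p-values and ~0.1% missing entries.

What it does **not** emulate: raw two-channel intensities or IDAT files,
bisulfite chemistry, genomic autocorrelation of methylation along a
chromosome, probe-specific (rather than class-wide) technical bias, and
correlated cell-type-by-treatment interactions beyond the planted shifts.
Passing tests therefore demonstrate that the *inference chain* is correct
and calibrated under its stated model, not that real arrays satisfy that
model.

## QC and normalization

**Greedycut** iteratively removes the probe or sample whose fraction of
detection p-values above `alpha = 0.01` is largest, until no entry fails;
ties between the worst row and worst column drop the row, and within-axis
ties resolve by input order, so the removal sequence is deterministic.

**BMIQ.** Type-I and type-II probe chemistries yield different beta
distributions. Per sample, a three-state beta mixture
(unmethylated/hemimethylated/methylated) is fitted by EM to each class
(moment-matching M-step, at most 200 iterations, relative log-likelihood
tolerance 1e-6, values clipped to [1e-6, 1 - 1e-6]). EM components are
initialized from the beta-scale anchors 0.3 and 0.7 rather than a plain
quantile split: on realistically bimodal-plus-shoulder data a tertile
split seeds the small hemimethylated component astride the methylated
mode and the EM settles into a poor local optimum (we observed the
class-distribution gap *widening* on some seeds under that
initialization). Type-II unmethylated- and methylated-state values are
quantile-mapped through the corresponding fitted type-I components;
middle-state values are linearly interpolated between the mapped state
boundaries; type-I values pass through untouched. If the two classes are
already statistically indistinguishable — two-sample KS statistic below
the 1%-level critical value `1.63 * sqrt(1/n_I + 1/n_II)` — the transform
is the identity. That guard makes the already-normalized case exact and
repeated application idempotent, which a refit-and-remap EM pipeline
cannot otherwise guarantee.

**Probe filters** have set-intersection semantics (order-independent):
drop non-CpG contexts, SNP-overlapping, cross-reactive and chromosome-Y
probes, and probes with SD strictly below 0.005. **kNN imputation**
replaces each missing entry by the mean of the `k = 10` nearest probes
(RMS distance over jointly observed samples; only probes observed at the
target sample are eligible). **Paired shifts** in global methylation,
LUMP and cell fractions are tested with a Wilcoxon signed-rank test using
Pratt zero-handling; for n ≤ 25 the exact null is computed by sign-flip
convolution over the signed midranks (which handles ties exactly), above
that a normal approximation with continuity correction.

## Deconvolution

`rpc_fractions()` regresses each sample's marker-probe betas on the
reference profiles with Huber robust regression (tuning constant 1.345,
IRLS, ≤ 100 iterations), truncates negative coefficients at zero and
rescales to sum to one. The closure to the simplex is a deliberate
divergence from the common implementation (which leaves coefficients
unnormalized): downstream the fractions serve as model covariates and a
common scale keeps them interpretable. `lump_score()` is
`min(1, mean(1 - beta over the panel) / 0.85)`; the 0.85 scale and panel
are stated conventions, since only the algorithm family is fixed by the
source. Samples with scores below 0.9 are excluded.

## Differential methylation

Models are fitted on beta values (an M-value transform is deliberately
not the default, matching the pipeline being reproduced). The paired
design is `~ 0 + time + subject` plus the monocyte fraction; the contrast
is post − pre, and the subject block makes it a within-subject
comparison, invariant to any per-subject constant. The single-time-point
design is `~ 0 + treatment` plus batch, age, ethnicity, diagnosis year
and immune content (cell fractions for blood); reference levels are the
earliest batch and the majority ethnicity. Constant covariates are
dropped with a warning; collinear designs are an error naming the
offending columns.

Per feature, OLS gives the contrast estimate, residual variance `s²` and
df. The empirical-Bayes prior `(d0, s0²)` is estimated by moment matching
on `log s²` through the Fisher digamma/trigamma equations (features with
`s² = 0` are excluded from estimation and shrink fully to the prior); the
posterior variance is `s2_post = (d0 s0² + df s²)/(d0 + df)`, the
moderated t has `df + d0` degrees of freedom, and when the log-variances
show no excess dispersion the prior df is infinite with `s0²` the mean
observed variance. The test suite verifies exact agreement with the
reference implementation of this moderation on shared fixtures. Reported
standard errors are `sd_unscaled * sqrt(s2_post)`. The ranking z-score is
`sign(effect) * qnorm(1 - p/2)`, computed on the log scale so it stays
finite for extreme p.

Significance is Bonferroni: `alpha / n_tests` at `alpha = 0.05`; with the
published universe sizes 588,798 / 41,207 / 525,100 / 40,271 this yields
the familiar cutoffs 8.49e-8, 1.21e-6, 9.52e-8 and 1.24e-6. Promoters are
the mean of member-probe betas per sample (the convention chosen here;
the source leaves the region summary unstated), with promoters defined as
1.5 kb upstream to 0.5 kb downstream of the TSS when built from
coordinates. Cross-dataset validation intersects features that are
significant with the same effect sign in every dataset.

## Gene-set enrichment

Genes are ranked by the promoter z-score (largest |z| promoter per gene;
ties broken by |effect| then gene id, so runs are reproducible). The
enrichment score is the signed maximum of the weighted running sum
(exponent 1; set sizes restricted to [10, 500] after intersection with
the ranked universe).

Two nulls are computed. The **gene-resampling null** draws same-size
random sets; the p-value is one-tailed on the observed sign with the
plus-one convention, and both the exceedance count and the denominator
run over the same-sign null draws. We deliberately do not divide by the
total permutation count: by exchangeability that estimator concentrates
null p-values below the sign frequency (~0.5) and is anti-conservative,
while the conditional version is uniform — the package's calibration
tests check exactly this. `NES` is the score divided by the mean |null
score| of matching sign. The **outcome-label null** permutes treatment
labels across individuals (covariates stay with their samples), reruns
model fitting, moderation, ranking and scoring per permutation (default
500; any all-one-label permutation is redrawn), and applies the same
conditional one-sided plus-one rule; a two-sided toggle compares |ES|
against all permutations. The label null is the more honest of the two
when features are correlated, because it preserves the correlation
structure under resampling; its resolution floor is one over one plus the
number of same-sign permutations.

## Effect attenuation

Treated single-time-point samples are binned by time since treatment
start into half-open strata [0, 0.5), [0.5, 2), [2, ∞) years — the
boundary 0.5 belongs to the middle stratum — with missing times labelled
`unspecified`. One joint intercept-free five-level model (shared
covariate adjustment, untreated as reference) yields each
stratum-vs-untreated effect as a contrast, with a single shared variance
moderation. The attenuation slope regresses late-comparison effects on
early-comparison effects **through the origin**: the scientific
hypothesis is proportional shrinkage of the same planted effects, which
has no intercept; an intercept toggle exists for sensitivity analysis.
Slopes are computed over causal/strong features (the pipeline uses the
early-comparison significant set when it is large enough, all features
otherwise). Under exponential decay the slope estimates
`E[2^(-t_late/h)] / E[2^(-t_early/h)]` over the realized stratum time
distributions; recovery is tested against that expectation, and the
limits behave as they must — slope ≈ 1 with no decay, ≈ 0 when the
half-life is short against the late stratum. A literal "instant" decay
is not testable this way: once the half-life drops below the early
stratum's own times, the early effects vanish too and the through-origin
slope is undefined, so the fast-decay check uses a 0.2-year half-life
(late/early expected ratio ~2e-4). `count_persistent()` reports, among
features significant in the latest comparison, those with sign-consistent
effects everywhere and those whose |effect| shrinks monotonically.

## Numerical conventions and degenerate inputs

* Beta values are clipped to [1e-6, 1 - 1e-6] before mixture EM; latent
  means in the generator are clipped to [1e-3, 1 - 1e-3], so planted
  shifts near the boundaries saturate (the decay closed-form tests
  exclude saturated probes).
* All randomness flows from explicit seeds; no exported function reads
  the global RNG state implicitly (tie-breaks are deterministic
  throughout), and rerunning `run_pipeline()` under one configuration is
  bit-identical — serialized-output equality is an acceptance check.
* Degenerate cases signal rather than guess: empty detection matrices,
  probes with no observed values, rank-deficient references, excessive
  marker dropout, zero residual df, all-zero ranking statistics, gene
  sets outside the size window, near-zero early-effect variance. An
  all-zero paired difference vector returns p = 1 with a warning.
* `ebayes_moderate()` needs ≥ 10 features for the prior; non-finite
  moment estimates fall back to the unmoderated t with a warning.

## Problem sizes used in validation

The shipped tests and the acceptance script run at desk scale, chosen so
each check exercises the regime it targets: QC oracles on 10×10 and
50×10 fixtures; deconvolution recovery on 100 samples × 280 markers
(per-type RMSE under 0.05); differential calibration on 5,000 probes ×
60 null pairs and power on 125 pairs (sensitivity above 0.9 at the
Bonferroni cutoff for |shift| = 0.1); GSEA calibration on ~150-300
promoter universes with 100 label permutations (scaled from the
reference analysis's 500, which only refines the attainable p floor);
attenuation on 1,200 probes × 450 samples. The full demo pipeline runs
in well under a minute on one CPU.

## Known limitations

* The three-state mapping transfers type-II probes onto the type-I
  scale only as well as the beta mixture fits; heavily skewed samples can
  leave a residual class gap above the identity guard, in which case
  repeated application makes small further adjustments.
* RPC assumes the reference spans the true cell types; contamination by
  an unmodelled type biases fractions (the LUMP filter catches gross
  cases only).
* The label-permutation null conditions on the observed sign; with very
  few same-sign permutations the p resolution is coarse.
* Promoter aggregation by unweighted probe means treats all member
  probes as exchangeable; probes with opposite-sign effects within one
  promoter cancel.
* The attenuation slope inherits regression-attenuation bias when early
  effects are noisy; the pipeline's default restriction to
  early-significant features keeps that bias small but selects for
  larger effects.
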