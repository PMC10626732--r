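# chemomethyl

Chemotherapy leaves a footprint in the blood DNA methylome: beta values at
hundreds of CpG sites shift after treatment, the shifts are attenuated in
patients sampled years after therapy, and whole biological processes (most
prominently olfactory-receptor gene promoters) move together. `chemomethyl`
re-implements the full inference chain used to detect and validate such
treatment-associated DNA-methylation changes, as a tested, reusable R
package:

* **QC and normalization** of probe-by-sample beta matrices: iterative
  Greedycut filtering on detection p-values, beta-mixture quantile (BMIQ)
  normalization of type-II probes, context/SNP/cross-reactive/chromosome-Y
  and low-variability (SD < 0.005) probe filters, k-nearest-neighbour
  imputation, and genome-wide methylation summaries.
* **Cell-composition deconvolution**: robust-partial-correlation (RPC)
  estimation of 7-cell-type blood fractions against a marker reference,
  LUMP immune-content scores, and the purity filter (LUMP >= 0.9).
* **Differential methylation**: per-probe and per-promoter linear models
  for a paired pre/post design (`~ 0 + time + subject + monocytes`) and a
  single-time-point treated/untreated design with batch, age, ethnicity,
  diagnosis-year and immune-content adjustment; empirical-Bayes variance
  moderation; Bonferroni calling with sign-aware cross-dataset
  intersection.
* **Gene-set enrichment**: pre-ranked weighted Kolmogorov–Smirnov
  enrichment scores over promoter z-scores, a gene-resampling permutation
  null, and an outcome-label permutation null that re-runs the whole
  model-fitting chain per permutation.
* **Effect attenuation**: time-since-treatment strata (<0.5 y, 0.5–2 y,
  >2 y, unspecified), a joint five-level stratified model, through-origin
  slopes of late-comparison effects on early-comparison effects, and
  persistence/direction-consistency counts.
* **A synthetic-cohort generator** with planted ground truth (causal CpGs
  and promoters, Dirichlet cell mixtures, exponential post-treatment
  decay, batch structure, type-II probe compression, beta-distributed
  array noise), so every stage is testable without patient data.

The moderated statistic is the usual empirical-Bayes t: per feature
`t = c'beta_hat / (sqrt(s2_post) * sd_unscaled)` with
`s2_post = (d0 s0^2 + df s^2) / (d0 + df)`, the prior `(d0, s0^2)`
estimated by moment matching on `log s^2`. The enrichment score of a set S
in a ranked list of N genes is the signed maximum of the running sum that
gains `|z|/sum_S |z|` at members and loses `1/(N - |S|)` at non-members.
The attenuation slope is the through-origin regression coefficient of
late-stratum effects on early-stratum effects; under exponential decay
with half-life h it estimates `E[2^(-t_late/h)] / E[2^(-t_early/h)]`.

## Worked example

```r
library(chemomethyl)

cfg <- pipeline_config(
  simulate = simulate_config(
    n_probes = 1000, n_promoters = 60, n_markers_per_type = 10,
    n_pairs = 15, n_treated = 40, n_untreated = 30,
    strata_props = c(0.34, 0.33, 0.33, 0), seed = 5),
  nperm_genes = 200, seed = 5)
res <- suppressWarnings(run_pipeline(cfg))

glance(res$results$paired_probes)
#> # A tibble: 1 × 5
#>   n_features    d0    s0_2 n_significant threshold
#>        <int> <dbl>   <dbl>         <int>     <dbl>
#> 1        940  6.08 0.00126            14 0.0000532

head(tidy(res$gsea), 3)
#> # A tibble: 3 × 7
#>   set_id  size     es   nes p_geneperm n_perm_used direction
#>   <chr>  <dbl>  <dbl> <dbl>      <dbl>       <dbl> <chr>
#> 1 set022    39 -0.548 -1.50     0.0267         200 suppressed
#> 2 set045    46 -0.524 -1.38     0.0490         200 suppressed
#> 3 set003    38  0.387  1.30     0.05           200 activated

res$attenuation$slopes$lt_0.5y_vs_gt_2y[c("slope", "stderr")]
#> $slope
#> [1] 0.1284171
#> $stderr
#> [1] 0.02948633
```

The `glance()` line says 940 probes survived QC, the variance prior is
worth ~6 extra degrees of freedom per feature, and 14 probes pass the
Bonferroni cutoff 0.05/940. The enrichment table ranks gene sets by their
permutation p; `direction` reads off the enrichment-score sign. The
attenuation slope ~0.13 says effects measured more than two years after
treatment are about an eighth of those measured within half a year — the
generator's planted one-year half-life integrated over the stratum time
distributions. `autoplot(res$gsea)`, `plot_volcano()`, and
`plot_attenuation()` draw the matching figures.

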