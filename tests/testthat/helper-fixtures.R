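# Small cohorts and fixtures shared across test files. Everything is built
# in code at test time under fixed seeds.

small_cohort <- function(seed = 7, n_probes = 800, n_pairs = 15,
                         n_treated = 40, n_untreated = 40, ...) {
  simulate_cohort(simulate_config(
    n_probes = n_probes, n_promoters = min(60, n_probes %/% 20),
    n_markers_per_type = 10,
    n_pairs = n_pairs, n_treated = n_treated, n_untreated = n_untreated,
    n_lump_probes = 20, seed = seed, ...))
}

# QC'd complete beta matrix for a cohort
qc_beta <- function(cohort, bmiq = FALSE) {
  gc <- greedycut_filter(cohort$detp)
  b <- cohort$beta[gc$probes, gc$samples, drop = FALSE]
  if (bmiq) b <- suppressWarnings(bmiq_normalize_matrix(b, cohort$annotation))
  b <- filter_probes(b, cohort$annotation)$beta
  knn_impute(b)
}

# a tiny paired sheet with known structure
toy_paired_sheet <- function(n = 4) {
  subj <- sprintf("P%02d", seq_len(n))
  tibble::tibble(
    sample_id = c(paste0(subj, "_pre"), paste0(subj, "_post")),
    subject_id = rep(subj, 2),
    timepoint = rep(c("pre", "post"), each = n),
    treated = rep(c(FALSE, TRUE), each = n))
}
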