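#' Pipeline configuration
#'
#' Collects every stage toggle and threshold with the analysis defaults:
#' Greedycut detection alpha 0.01, probe SD floor 0.005, LUMP purity
#' minimum 0.9, family-wise alpha 0.05, GSEA size window 10-500 with
#' exponent 1, 10,000 gene permutations and 500 outcome-label
#' permutations. Serializes losslessly to YAML (JSON fallback).
#'
#' @param simulate a [simulate_config()]; `NULL` when supplying data.
#' @param detection_alpha Greedycut detection p cutoff.
#' @param sd_min probe SD filter floor.
#' @param purity_min LUMP purity cutoff.
#' @param alpha family-wise error rate for Bonferroni calling.
#' @param knn_k imputation neighbour count.
#' @param gsea_min_size,gsea_max_size,gsea_exponent GSEA parameters.
#' @param nperm_genes,nperm_labels permutation counts.
#' @param run_bmiq,run_gsea,run_label_perm,run_attenuation stage toggles.
#' @param seed master seed; all stage seeds derive from it.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = simulate_config(),
                            detection_alpha = 0.01, sd_min = 0.005,
                            purity_min = 0.9, alpha = 0.05, knn_k = 10,
                            gsea_min_size = 10, gsea_max_size = 500,
                            gsea_exponent = 1, nperm_genes = 10000,
                            nperm_labels = 500, run_bmiq = TRUE,
                            run_gsea = TRUE, run_label_perm = FALSE,
                            run_attenuation = TRUE, seed = 1L) {
  structure(list(simulate = simulate, detection_alpha = detection_alpha,
                 sd_min = sd_min, purity_min = purity_min, alpha = alpha,
                 knn_k = knn_k, gsea_min_size = gsea_min_size,
                 gsea_max_size = gsea_max_size,
                 gsea_exponent = gsea_exponent,
                 nperm_genes = nperm_genes, nperm_labels = nperm_labels,
                 run_bmiq = run_bmiq, run_gsea = run_gsea,
                 run_label_perm = run_label_perm,
                 run_attenuation = run_attenuation, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  if (!is.null(lst$simulate)) {
    sim <- unclass(lst$simulate)
    sim$dirichlet_alpha <- as.list(sim$dirichlet_alpha)  # keep names in YAML
    lst$simulate <- sim
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  sim <- lst$simulate
  lst$simulate <- NULL
  cfg <- do.call(pipeline_config, c(lst, list(simulate = NULL)))
  if (!is.null(sim)) {
    sim$dirichlet_alpha <- unlist(sim$dirichlet_alpha)
    sim$strata_props <- unlist(sim$strata_props)
    cfg$simulate <- do.call(simulate_config, sim)
  }
  cfg
}

#' Run the full analysis pipeline on a simulated or supplied cohort
#'
#' Executes simulate (optional) -> Greedycut -> BMIQ -> probe filters ->
#' kNN imputation -> global methylation -> deconvolution (RPC fractions,
#' LUMP, purity filter) -> paired differential analysis (probes and
#' promoters) -> single-time-point differential analysis -> GSEA (with an
#' optional outcome-label permutation null) -> time-stratified attenuation.
#' Every stage's randomness derives from the configuration seed, so reruns
#' with the same configuration are identical.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built cohort (the list [simulate_cohort()]
#'   returns); when `NULL` the configuration's `simulate` field is used.
#' @param gene_sets optional named list of gene sets; by default a
#'   collection with planted enriched sets is generated from the truth.
#' @return list of stage results plus a provenance `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL, gene_sets = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    if (is.null(config$simulate))
      stop("no cohort supplied and no simulation configured", call. = FALSE)
    cohort <- simulate_cohort(config$simulate)
  }
  qc_log <- list()

  ## QC -------------------------------------------------------------------
  gc <- greedycut_filter(cohort$detp, alpha = config$detection_alpha)
  qc_log$greedycut <- gc$report
  beta <- cohort$beta[gc$probes, gc$samples, drop = FALSE]
  if (config$run_bmiq)
    beta <- bmiq_normalize_matrix(beta, cohort$annotation)
  fp <- filter_probes(beta, cohort$annotation, sd_min = config$sd_min)
  qc_log$probe_filters <- fp$counts
  beta <- knn_impute(fp$beta, k = config$knn_k)
  global <- global_methylation(beta)

  ## deconvolution ---------------------------------------------------------
  fractions <- rpc_fractions(beta, cohort$reference)
  lump <- lump_score(beta, cohort$lump_probes)
  pf <- purity_filter(lump, min_score = config$purity_min)
  qc_log$purity <- pf$report
  beta <- beta[, pf$samples, drop = FALSE]
  sheet <- cohort$sheet[cohort$sheet$sample_id %in% pf$samples, ]

  ## differential methylation ---------------------------------------------
  regions <- build_region_map(cohort$annotation)
  results <- list()
  paired_sheet <- dplyr::filter(sheet, .data$arm == "paired")
  # drop pairs broken by sample-level QC
  if (nrow(paired_sheet)) {
    whole <- names(which(table(paired_sheet$subject_id) == 2))
    paired_sheet <- dplyr::filter(paired_sheet, .data$subject_id %in% whole)
  }
  if (nrow(paired_sheet) >= 4) {
    mono <- fractions[[grep("Mono|leukocyte",
                            names(fractions), value = TRUE)[1]]]
    paired_sheet$monocytes <- mono[match(paired_sheet$sample_id,
                                         fractions$sample_id)]
    dsg <- build_design(paired_sheet, "paired", adjust = "monocytes")
    fits <- fit_feature_models(beta[, paired_sheet$sample_id], dsg)
    res <- ebayes_moderate(fits)
    thr <- bonferroni_threshold(nrow(beta), config$alpha)
    results$paired_probes <- call_significant(res, thr)
    prom_beta <- aggregate_promoters(beta[, paired_sheet$sample_id], regions)
    pfits <- fit_feature_models(prom_beta, dsg)
    pres <- ebayes_moderate(pfits)
    pthr <- bonferroni_threshold(nrow(prom_beta), config$alpha)
    results$paired_promoters <- call_significant(pres, pthr)
  }
  single_sheet <- dplyr::filter(sheet, .data$arm == "single")
  gsea <- label_perm <- attenuation <- NULL
  if (nrow(single_sheet) >= 4 && any(single_sheet$treated) &&
      any(!single_sheet$treated)) {
    single_sheet$lump <- lump$lump[match(single_sheet$sample_id,
                                         lump$sample_id)]
    adj <- intersect(c("batch", "age", "ethnicity", "diagnosis_year", "lump"),
                     names(single_sheet))
    adj <- adj[vapply(adj, function(a)
      length(unique(single_sheet[[a]])) > 1, logical(1))]
    sbeta <- beta[, single_sheet$sample_id, drop = FALSE]
    dsg <- build_design(single_sheet, "single", adjust = adj)
    fits <- fit_feature_models(sbeta, dsg)
    res <- ebayes_moderate(fits)
    thr <- bonferroni_threshold(nrow(sbeta), config$alpha)
    results$single_probes <- call_significant(res, thr)
    prom_beta <- aggregate_promoters(sbeta, regions)
    pfits <- fit_feature_models(prom_beta, dsg)
    pres <- ebayes_moderate(pfits)
    pthr <- bonferroni_threshold(nrow(prom_beta), config$alpha)
    results$single_promoters <- call_significant(pres, pthr)
    gene_map <- attr(prom_beta, "gene_id")

    if (config$run_gsea) {
      if (is.null(gene_sets))
        gene_sets <- make_gene_sets(cohort$truth,
                                    universe = unname(gene_map),
                                    seed = config$seed + 101L)
      gsea <- run_gsea(results$single_promoters, gene_sets, gene_map,
                       n_perm = max(100, config$nperm_genes),
                       seed = config$seed + 202L,
                       exponent = config$gsea_exponent,
                       min_size = config$gsea_min_size,
                       max_size = config$gsea_max_size)
      if (config$run_label_perm)
        label_perm <- label_permutation_null(
          prom_beta, single_sheet, gene_map, gene_sets,
          n_perm = config$nperm_labels, seed = config$seed + 303L,
          adjust = adj, exponent = config$gsea_exponent)
    }
    if (config$run_attenuation) {
      strata <- stratify_by_time(single_sheet)
      sres <- fit_strata_models(sbeta, single_sheet, strata, adjust = adj)
      comp <- intersect(c("lt_0.5y", "0.5_2y", "gt_2y"), names(sres))
      slopes <- list()
      if (length(comp) >= 2) {
        early <- sres[[comp[1]]]
        sig_early <- early$feature_id[
          early$p < bonferroni_threshold(nrow(sbeta), config$alpha)]
        base <- if (length(sig_early) >= 10) sig_early else early$feature_id
        for (lv in comp[-1]) {
          m <- match(base, sres[[lv]]$feature_id)
          sl <- attenuation_slope(early$effect[match(base, early$feature_id)],
                                  sres[[lv]]$effect[m])
          slopes[[paste0(comp[1], "_vs_", lv)]] <- sl
        }
      }
      attenuation <- list(
        strata_results = sres, slopes = slopes,
        persistence = count_persistent(
          sres, bonferroni_threshold(nrow(sbeta), config$alpha)))
    }
  }

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    n_probes_retained = nrow(beta),
    n_samples_retained = ncol(beta),
    stages = c("simulate", "greedycut", if (config$run_bmiq) "bmiq",
               "filter", "impute", "deconvolve", "diff",
               if (config$run_gsea) "gsea",
               if (config$run_label_perm) "label_perm",
               if (config$run_attenuation) "attenuation"))
  list(beta = beta, qc = qc_log, global_methylation = global,
       fractions = fractions, lump = lump, results = results, gsea = gsea,
       label_perm = label_perm, attenuation = attenuation,
       truth = cohort$truth, manifest = manifest)
}

#' Deterministic toy fixtures for the test suite
#'
#' Regenerates, from one seed, the small matrices the unit tests exercise:
#' a 10x10 detection-p matrix with scattered failures, a 50x10 beta matrix
#' with missing entries for imputation, a 20-gene ranked list, and a tiny
#' paired cohort.
#'
#' @param seed integer seed.
#' @return named list of fixtures.
#' @export
generate_fixtures <- function(seed = 42L) {
  set.seed(seed)
  detp <- matrix(stats::runif(100, 0, 0.005), 10, 10,
                 dimnames = list(paste0("p", 1:10), paste0("s", 1:10)))
  detp[sample.int(100, 12)] <- stats::runif(12, 0.02, 1)
  impute_beta <- matrix(stats::runif(500), 50, 10,
                        dimnames = list(paste0("p", 1:50), paste0("s", 1:10)))
  impute_beta[sample.int(500, 20)] <- NA
  ranked <- tibble::tibble(gene_id = paste0("g", sprintf("%02d", 1:20)),
                           stat = sort(stats::rnorm(20), decreasing = TRUE))
  cohort <- simulate_cohort(simulate_config(
    n_probes = 300, n_promoters = 30, n_markers_per_type = 5,
    n_pairs = 10, n_treated = 12, n_untreated = 12, n_lump_probes = 10,
    seed = seed))
  list(detp = detp, impute_beta = impute_beta, ranked = ranked,
       cohort = cohort)
}
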