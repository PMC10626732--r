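#' Simulation configuration for a synthetic methylation cohort
#'
#' Collects every knob of the cohort generator. Defaults describe the study
#' design the pipeline targets: a paired pre-/post-treatment arm of 125
#' subjects and a single-time-point arm of 1,066 treated and 742 untreated
#' blood donors (207/130 for saliva), 7-cell-type blood mixtures with a
#' granulocyte-dominated Dirichlet prior, a bimodal background methylome with
#' genome-wide mean near 0.655, beta-distributed array noise, batch offsets,
#' and exponential post-treatment decay of planted effects. The probe universe
#' defaults to a desk-scale 5,000 probes grouped into 400 promoters.
#'
#' @param n_probes number of CpG probes.
#' @param n_promoters number of promoter regions (first
#'   `n_promoters * probes_per_promoter` probes are promoter members).
#' @param probes_per_promoter probes per promoter region.
#' @param n_celltypes number of reference cell types (7 for blood,
#'   forced to 2 for saliva: leukocyte/epithelial).
#' @param n_markers_per_type type-specific marker probes per cell type.
#' @param n_pairs subjects in the paired pre/post arm.
#' @param n_treated,n_untreated single-time-point arm sizes.
#' @param specimen `"blood"` or `"saliva"`.
#' @param frac_causal_probes fraction of probes carrying a planted
#'   treatment effect.
#' @param effect_size_delta mean planted shift on the beta scale.
#' @param decay_halflife half-life (years) of post-treatment effect decay.
#' @param batch_count number of processing batches.
#' @param noise_precision beta-distribution concentration of observation
#'   noise; `Inf` means noiseless.
#' @param dirichlet_alpha Dirichlet concentration vector over cell types;
#'   `NULL` uses specimen-specific defaults.
#' @param strata_props proportions of treated single-time-point samples in
#'   the four time strata (<0.5 y, 0.5-2 y, >2 y, unspecified).
#' @param det_fail_frac fraction of probes made unreliable (elevated
#'   detection p in about half of their samples); a thin `1e-4` scatter of
#'   isolated entry failures is added on top.
#' @param missing_frac fraction of beta entries set missing.
#' @param n_lump_probes number of leukocyte-unmethylated purity probes.
#' @param n_low_purity number of planted low-purity single-arm samples.
#' @param typeII_shrink logit-scale divisor compressing type-II probe
#'   betas toward 0.5 (the distortion BMIQ corrects).
#' @param batch_sd,subject_sd SDs of batch and subject offsets (beta scale).
#' @param single_time_override optional vector of times (years) recycled
#'   over treated single-time-point samples, replacing the drawn times.
#' @param seed integer seed; the whole emitted bundle is a deterministic
#'   function of the configuration.
#' @return a `sim_config` list.
#' @export
simulate_config <- function(n_probes = 5000, n_promoters = 400,
                            probes_per_promoter = 4,
                            n_celltypes = 7, n_markers_per_type = 40,
                            n_pairs = 125, n_treated = 1066, n_untreated = 742,
                            specimen = c("blood", "saliva"),
                            frac_causal_probes = 0.02,
                            effect_size_delta = 0.10,
                            decay_halflife = 1, batch_count = 2,
                            noise_precision = 100,
                            dirichlet_alpha = NULL,
                            strata_props = c(0.19, 0.35, 0.37, 0.09),
                            det_fail_frac = 0.002, missing_frac = 0.001,
                            n_lump_probes = 50, n_low_purity = 0,
                            typeII_shrink = 1.4,
                            batch_sd = 0.005, subject_sd = 0.01,
                            single_time_override = NULL,
                            seed = 1L) {
  specimen <- match.arg(specimen)
  if (specimen == "saliva") {
    n_celltypes <- 2L
    if (n_treated == 1066 && n_untreated == 742) {
      n_treated <- 207L; n_untreated <- 130L
    }
  }
  counts <- c(n_probes = n_probes, n_promoters = n_promoters,
              probes_per_promoter = probes_per_promoter,
              n_celltypes = n_celltypes, n_markers_per_type = n_markers_per_type,
              batch_count = batch_count)
  if (any(counts <= 0)) stop("all counts must be > 0", call. = FALSE)
  if (n_pairs < 0 || n_treated < 0 || n_untreated < 0)
    stop("arm sizes must be non-negative", call. = FALSE)
  props <- c(frac_causal_probes, det_fail_frac, missing_frac)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (is.null(dirichlet_alpha)) {
    dirichlet_alpha <- if (specimen == "blood")
      c(B = 0.5, NK = 1, CD4T = 1.5, CD8T = 4, Mono = 3,
        Neutro = 38, Eosino = 2)
    else c(leukocyte = 6, epithelial = 4)
  }
  if (length(dirichlet_alpha) != n_celltypes || any(dirichlet_alpha <= 0))
    stop("dirichlet_alpha must be strictly positive, one entry per cell type",
         call. = FALSE)
  if (n_markers_per_type * n_celltypes > n_probes)
    stop("marker probes exceed probe universe", call. = FALSE)
  if (abs(sum(strata_props) - 1) > 1e-8 || length(strata_props) != 4)
    stop("strata_props must be 4 proportions summing to 1", call. = FALSE)
  structure(list(
    n_probes = as.integer(n_probes), n_promoters = as.integer(n_promoters),
    probes_per_promoter = as.integer(probes_per_promoter),
    n_celltypes = as.integer(n_celltypes),
    n_markers_per_type = as.integer(n_markers_per_type),
    n_pairs = as.integer(n_pairs), n_treated = as.integer(n_treated),
    n_untreated = as.integer(n_untreated), specimen = specimen,
    frac_causal_probes = frac_causal_probes,
    effect_size_delta = effect_size_delta,
    decay_halflife = decay_halflife, batch_count = as.integer(batch_count),
    noise_precision = noise_precision, dirichlet_alpha = dirichlet_alpha,
    strata_props = strata_props, det_fail_frac = det_fail_frac,
    missing_frac = missing_frac, n_lump_probes = as.integer(n_lump_probes),
    n_low_purity = as.integer(n_low_purity),
    typeII_shrink = typeII_shrink, batch_sd = batch_sd,
    subject_sd = subject_sd, single_time_override = single_time_override,
    seed = as.integer(seed)), class = "sim_config")
}

#' Synthetic reference methylome with type-specific marker blocks
#'
#' Builds a probes-by-cell-types beta matrix in which each cell type owns a
#' block of marker probes where its methylation differs from every other
#' type by at least 0.5, alternating hypo- and hypermethylated marker
#' blocks; non-marker rows share a common bimodal baseline across types.
#' Marker probes occupy the last `n_markers_per_type * n_celltypes` rows.
#'
#' @param n_probes rows of the reference.
#' @param n_celltypes columns (cell types).
#' @param n_markers_per_type marker probes per type.
#' @param seed integer seed.
#' @param celltype_names optional column names.
#' @return beta matrix with attributes `marker_probes` (row indices) and
#'   `marker_type` (owning cell type per marker row).
#' @export
make_reference_profiles <- function(n_probes, n_celltypes,
                                    n_markers_per_type, seed = 1L,
                                    celltype_names = NULL) {
  if (n_probes <= 0 || n_celltypes <= 0 || n_markers_per_type <= 0)
    stop("dimensions must be positive", call. = FALSE)
  if (n_markers_per_type * n_celltypes > n_probes)
    stop("marker probes exceed probe universe", call. = FALSE)
  set.seed(seed)
  if (is.null(celltype_names))
    celltype_names <- paste0("ct", seq_len(n_celltypes))
  # trimodal background: unmethylated / hemimethylated / methylated modes,
  # weighted to give a genome-wide mean near 0.655
  mode <- sample(1:3, n_probes, replace = TRUE, prob = c(0.22, 0.12, 0.66))
  baseline <- c(stats::runif(n_probes, 0.03, 0.15),
                stats::runif(n_probes, 0.40, 0.60),
                stats::runif(n_probes, 0.78, 0.97))[
                  n_probes * (mode - 1) + seq_len(n_probes)]
  ref <- matrix(rep(baseline, n_celltypes), ncol = n_celltypes,
                dimnames = list(sprintf("cg%07d", seq_len(n_probes)),
                                celltype_names))
  n_mark <- n_markers_per_type * n_celltypes
  marker_rows <- seq(n_probes - n_mark + 1, n_probes)
  marker_type <- rep(seq_len(n_celltypes), each = n_markers_per_type)
  for (k in seq_len(n_celltypes)) {
    rows <- marker_rows[marker_type == k]
    if (k %% 2 == 1) {     # hypomethylated in its own type
      ref[rows, ] <- stats::runif(length(rows) * n_celltypes, 0.72, 0.92)
      ref[rows, k] <- stats::runif(length(rows), 0.02, 0.08)
    } else {               # hypermethylated in its own type
      ref[rows, ] <- stats::runif(length(rows) * n_celltypes, 0.05, 0.30)
      ref[rows, k] <- stats::runif(length(rows), 0.90, 0.97)
    }
  }
  attr(ref, "marker_probes") <- marker_rows
  attr(ref, "marker_type") <- marker_type
  ref
}

stratum_levels <- c("untreated", "lt_0.5y", "0.5_2y", "gt_2y", "unspecified")

draw_stratum_times <- function(n, props) {
  s <- sample(stratum_levels[2:5], n, replace = TRUE, prob = props)
  t <- numeric(n)
  t[s == "lt_0.5y"] <- stats::runif(sum(s == "lt_0.5y"), 0, 0.5)
  t[s == "0.5_2y"] <- stats::runif(sum(s == "0.5_2y"), 0.5, 2)
  t[s == "gt_2y"]  <- stats::runif(sum(s == "gt_2y"), 2, 6)
  t[s == "unspecified"] <- stats::runif(sum(s == "unspecified"), 0, 6)
  list(stratum = s, time = t)
}

#' Simulate a full synthetic cohort with planted ground truth
#'
#' Emits a probes-by-samples beta matrix, a matched detection-p matrix, a
#' sample sheet covering a paired pre/post arm and a single-time-point
#' treated/untreated arm, a probe annotation table, the cell-type reference
#' used, and a truth record. Per sample the latent methylation is the
#' reference mixed by Dirichlet cell fractions at marker probes and a
#' bimodal background elsewhere; treated samples receive the planted signed
#' shifts at causal probes scaled by `2^(-t / halflife)` with `t` years
#' since treatment start; batch and (paired-arm) subject offsets are added;
#' type-II probes are compressed toward 0.5 on the logit scale; observation
#' noise is `Beta(mu * nu, (1 - mu) * nu)` with `nu = noise_precision`.
#'
#' @param config a [simulate_config()] object.
#' @return list with elements `beta`, `detp`, `sheet` (tibble), `annotation`
#'   (tibble), `reference`, `lump_probes`, and `truth` (a list holding
#'   causal probe/promoter ids, signed per-probe shifts, true cell
#'   fractions, latent means at causal probes, strata, and the half-life).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  ct_names <- names(cfg$dirichlet_alpha)
  ref <- make_reference_profiles(cfg$n_probes, cfg$n_celltypes,
                                 cfg$n_markers_per_type, seed = cfg$seed,
                                 celltype_names = ct_names)
  set.seed(cfg$seed + 1L)
  np <- cfg$n_probes
  probe_ids <- rownames(ref)
  marker_rows <- attr(ref, "marker_probes")
  baseline <- ref[, 1]            # non-marker rows equal across types

  ## ---- annotation -------------------------------------------------------
  n_prom_probes <- cfg$n_promoters * cfg$probes_per_promoter
  if (n_prom_probes > np - length(marker_rows) - cfg$n_lump_probes)
    stop("promoter probes exceed available background probes", call. = FALSE)
  promoter_id <- rep(NA_character_, np)
  gene_id <- rep(NA_character_, np)
  prom_rows <- seq_len(n_prom_probes)
  promoter_id[prom_rows] <- rep(sprintf("prom%04d", seq_len(cfg$n_promoters)),
                                each = cfg$probes_per_promoter)
  gene_id[prom_rows] <- rep(sprintf("gene%04d", seq_len(cfg$n_promoters)),
                            each = cfg$probes_per_promoter)
  bg_free <- setdiff(seq_len(np), c(prom_rows, marker_rows))
  lump_rows <- sort(sample(bg_free, cfg$n_lump_probes))
  bg_free <- setdiff(bg_free, lump_rows)

  design_class <- ifelse(stats::runif(np) < 0.3, "I", "II")
  design_class[c(marker_rows, lump_rows)] <- "I"
  context <- sample(c("CG", "CC", "CAG", "CAH", "CTG", "CTH", "Other"), np,
                    replace = TRUE,
                    prob = c(0.97, rep(0.005, 6)))
  context[c(marker_rows, lump_rows)] <- "CG"
  snp_overlap <- stats::runif(np) < 0.01
  cross_reactive <- stats::runif(np) < 0.01
  snp_overlap[c(marker_rows, lump_rows)] <- FALSE
  cross_reactive[c(marker_rows, lump_rows)] <- FALSE
  chrom <- sample(c(as.character(1:22), "X"), np, replace = TRUE)
  y_candidates <- intersect(bg_free, which(stats::runif(np) < 0.004))
  chrom[y_candidates] <- "Y"
  position <- sort(sample.int(2^28, np))

  ## ---- causal features --------------------------------------------------
  n_causal <- round(cfg$frac_causal_probes * np)
  if (n_causal > np) stop("causal count exceeds probe count", call. = FALSE)
  n_causal_prom <- min(cfg$n_promoters,
                       max(if (n_causal > 0) 1L else 0L,
                           round(0.6 * n_causal / cfg$probes_per_promoter)))
  causal_proms <- if (n_causal_prom > 0)
    sort(sample(cfg$n_promoters, n_causal_prom)) else integer(0)
  causal_rows <- prom_rows[promoter_id[prom_rows] %in%
                             sprintf("prom%04d", causal_proms)]
  n_extra <- max(0L, n_causal - length(causal_rows))
  extra_rows <- if (n_extra > 0) sample(bg_free, min(n_extra, length(bg_free)))
                else integer(0)
  causal_rows <- sort(c(causal_rows, extra_rows))
  delta <- rep(0, np)
  if (length(causal_proms)) {
    prom_sign <- sample(c(-1, 1), length(causal_proms), replace = TRUE)
    names(prom_sign) <- sprintf("prom%04d", causal_proms)
  } else prom_sign <- numeric(0)
  for (r in causal_rows) {
    s <- if (!is.na(promoter_id[r]) && promoter_id[r] %in% names(prom_sign))
      prom_sign[promoter_id[r]] else sample(c(-1, 1), 1)
    delta[r] <- s * cfg$effect_size_delta * stats::runif(1, 0.75, 1.25)
  }

  ## ---- sample sheet -----------------------------------------------------
  sheets <- list()
  if (cfg$n_pairs > 0) {
    subj <- sprintf("P%03d", seq_len(cfg$n_pairs))
    batch <- sample(cfg$batch_count, cfg$n_pairs, replace = TRUE)
    age <- round(stats::rnorm(cfg$n_pairs, 56, 8))
    eth <- sample(c("Chinese", "Other"), cfg$n_pairs, replace = TRUE,
                  prob = c(0.79, 0.21))
    dy <- sample(2010:2018, cfg$n_pairs, replace = TRUE)
    sheets$paired <- tibble::tibble(
      sample_id = c(paste0(subj, "_pre"), paste0(subj, "_post")),
      subject_id = rep(subj, 2),
      arm = "paired",
      timepoint = rep(c("pre", "post"), each = cfg$n_pairs),
      treated = rep(c(FALSE, TRUE), each = cfg$n_pairs),
      specimen = cfg$specimen,
      batch = rep(batch, 2), age = rep(age, 2), ethnicity = rep(eth, 2),
      diagnosis_year = rep(dy, 2),
      time_from_treatment = rep(c(NA_real_, 0), each = cfg$n_pairs),
      stratum = rep(c("untreated", "lt_0.5y"), each = cfg$n_pairs))
  }
  n_single <- cfg$n_treated + cfg$n_untreated
  if (n_single > 0) {
    subj <- sprintf("S%04d", seq_len(n_single))
    treated <- rep(c(TRUE, FALSE), c(cfg$n_treated, cfg$n_untreated))
    st <- draw_stratum_times(cfg$n_treated, cfg$strata_props)
    if (!is.null(cfg$single_time_override) && cfg$n_treated > 0) {
      st$time <- rep_len(cfg$single_time_override, cfg$n_treated)
      st$stratum <- cut(st$time, c(0, 0.5, 2, Inf),
                        labels = stratum_levels[2:4], right = FALSE,
                        include.lowest = FALSE)
      st$stratum <- as.character(st$stratum)
      st$stratum[st$time == 0] <- "lt_0.5y"
    }
    time_true <- c(st$time, rep(NA_real_, cfg$n_untreated))
    stratum <- c(st$stratum, rep("untreated", cfg$n_untreated))
    time_rec <- time_true
    time_rec[stratum == "unspecified"] <- NA_real_
    sheets$single <- tibble::tibble(
      sample_id = subj, subject_id = subj, arm = "single",
      timepoint = NA_character_, treated = treated, specimen = cfg$specimen,
      batch = sample(cfg$batch_count, n_single, replace = TRUE),
      age = round(stats::rnorm(n_single, 58, 9)),
      ethnicity = sample(c("Chinese", "Other"), n_single, replace = TRUE,
                         prob = c(0.79, 0.21)),
      diagnosis_year = sample(2010:2018, n_single, replace = TRUE),
      time_from_treatment = time_rec, stratum = stratum)
    attr(sheets$single, "time_true") <- time_true
  }
  sheet <- dplyr::bind_rows(sheets)
  ns <- nrow(sheet)
  time_true_all <- sheet$time_from_treatment
  if (!is.null(sheets$single)) {
    idx <- sheet$arm == "single"
    time_true_all[idx] <- attr(sheets$single, "time_true")
  }

  ## ---- latent means -----------------------------------------------------
  fractions <- rdirichlet(ns, cfg$dirichlet_alpha)
  colnames(fractions) <- ct_names
  rownames(fractions) <- sheet$sample_id
  mu <- matrix(rep(baseline, ns), nrow = np,
               dimnames = list(probe_ids, sheet$sample_id))
  mu[marker_rows, ] <- ref[marker_rows, ] %*% t(fractions)
  lump_base <- stats::runif(length(lump_rows), 0.13, 0.19)
  if (cfg$specimen == "blood") {
    mu[lump_rows, ] <- lump_base
  } else {
    leuk <- fractions[, "leukocyte"]
    mu[lump_rows, ] <- outer(lump_base, leuk) +
      0.85 * outer(rep(1, length(lump_rows)), 1 - leuk)
  }
  low_purity_ids <- character(0)
  if (cfg$n_low_purity > 0 && !is.null(sheets$single)) {
    idx <- which(sheet$arm == "single")
    pick <- sample(idx, min(cfg$n_low_purity, length(idx)))
    low_purity_ids <- sheet$sample_id[pick]
    mu[lump_rows, pick] <- stats::runif(length(lump_rows) * length(pick),
                                        0.35, 0.50)
  }
  bg_rows <- setdiff(seq_len(np), c(marker_rows, lump_rows))
  # subject offsets (paired arm shares the offset within subject)
  subj_off <- stats::rnorm(length(unique(sheet$subject_id)), 0, cfg$subject_sd)
  names(subj_off) <- unique(sheet$subject_id)
  batch_off <- stats::rnorm(cfg$batch_count, 0, cfg$batch_sd)
  shift <- subj_off[sheet$subject_id] + batch_off[sheet$batch]
  mu[bg_rows, ] <- mu[bg_rows, ] + rep(shift, each = length(bg_rows))
  # planted treatment effects with exponential decay
  treated_idx <- which(sheet$treated)
  if (length(treated_idx) && length(causal_rows)) {
    tvec <- time_true_all[treated_idx]
    tvec[is.na(tvec)] <- 0
    decay <- 2^(-tvec / cfg$decay_halflife)
    mu[causal_rows, treated_idx] <- mu[causal_rows, treated_idx] +
      outer(delta[causal_rows], decay)
  }
  mu <- clip01(mu, 1e-3)
  latent_causal <- mu[causal_rows, , drop = FALSE]
  # type-II compression (the distortion BMIQ corrects)
  ii <- which(design_class == "II")
  mu_obs <- mu
  if (length(ii) && cfg$typeII_shrink != 1)
    mu_obs[ii, ] <- stats::plogis(stats::qlogis(mu[ii, ]) / cfg$typeII_shrink)

  ## ---- observation noise, detection p, missingness ----------------------
  if (is.finite(cfg$noise_precision)) {
    nu <- cfg$noise_precision
    beta <- matrix(stats::rbeta(np * ns, mu_obs * nu, (1 - mu_obs) * nu),
                   nrow = np, dimnames = dimnames(mu_obs))
  } else beta <- mu_obs
  detp <- matrix(stats::runif(np * ns, 0, 0.005), nrow = np,
                 dimnames = dimnames(mu_obs))
  # unreliable probes fail in many samples (what Greedycut removes), plus a
  # thin scatter of isolated background failures
  n_bad <- round(cfg$det_fail_frac * np)
  if (n_bad > 0) {
    bad_rows <- sample.int(np, n_bad)
    hit <- matrix(stats::runif(n_bad * ns) < 0.5, nrow = n_bad)
    block <- detp[bad_rows, , drop = FALSE]
    block[hit] <- stats::runif(sum(hit), 0.02, 1)
    detp[bad_rows, ] <- block
  }
  n_scatter <- round(1e-4 * np * ns)
  if (n_scatter > 0)
    detp[sample.int(np * ns, n_scatter)] <- stats::runif(n_scatter, 0.02, 1)
  n_miss <- round(cfg$missing_frac * np * ns)
  if (n_miss > 0) beta[sample.int(np * ns, n_miss)] <- NA_real_

  annotation <- tibble::tibble(
    probe_id = probe_ids, chrom = chrom, position = position,
    design_class = design_class, context = context,
    snp_overlap = snp_overlap, cross_reactive = cross_reactive,
    promoter_id = promoter_id, gene_id = gene_id)

  truth <- list(
    causal_probe_ids = probe_ids[causal_rows],
    causal_promoter_ids = sprintf("prom%04d", causal_proms),
    causal_gene_ids = sprintf("gene%04d", causal_proms),
    causal_gene_signs = if (length(causal_proms))
      stats::setNames(unname(prom_sign),
                      sprintf("gene%04d", causal_proms)) else numeric(0),
    true_delta_per_probe = stats::setNames(delta[causal_rows],
                                           probe_ids[causal_rows]),
    true_fractions = fractions,
    true_decay_halflife = cfg$decay_halflife,
    time_from_treatment_true = stats::setNames(time_true_all, sheet$sample_id),
    stratum = stats::setNames(sheet$stratum, sheet$sample_id),
    low_purity_ids = low_purity_ids,
    latent_causal = latent_causal,
    enriched_set_ids = character(0))

  list(beta = beta, detp = detp, sheet = sheet, annotation = annotation,
       reference = ref[marker_rows, , drop = FALSE],
       lump_probes = probe_ids[lump_rows], truth = truth, config = cfg)
}

#' Generate a synthetic gene-set collection with planted enriched sets
#'
#' Builds `n_sets` gene sets over the cohort's gene universe; `n_enriched`
#' of them draw most (default 80%) of their members from the causal genes
#' recorded in the truth record, the rest are uniform draws. Set sizes are
#' drawn within `set_size_range`, kept inside the conventional GSEA
#' bounds of 10 and 500.
#'
#' @param truth truth record from [simulate_cohort()].
#' @param universe character vector of all gene ids rankable downstream.
#' @param n_sets number of sets.
#' @param set_size_range length-2 integer range of set sizes.
#' @param n_enriched number of sets planted to over-represent causal genes.
#' @param frac_causal_members fraction of an enriched set drawn from
#'   causal genes (down-weighted if fewer causal genes exist).
#' @param direction `"both"` draws enriched members from all causal genes;
#'   `"hyper"`/`"hypo"` restrict to genes whose planted shift is positive/
#'   negative, so the planted sets concentrate at one ranking extreme.
#' @param seed integer seed.
#' @return named list of character vectors (a GMT collection); the truth
#'   record is returned updated in attribute `"truth"` with
#'   `enriched_set_ids` filled in.
#' @export
make_gene_sets <- function(truth, universe, n_sets = 50,
                           set_size_range = c(10, 50), n_enriched = 3,
                           frac_causal_members = 0.8,
                           direction = c("both", "hyper", "hypo"),
                           seed = 1L) {
  direction <- match.arg(direction)
  if (n_enriched > n_sets)
    stop("n_enriched cannot exceed n_sets", call. = FALSE)
  if (set_size_range[1] < 10 || set_size_range[2] > 500 ||
      set_size_range[1] > set_size_range[2])
    stop("set sizes must lie within [10, 500]", call. = FALSE)
  set.seed(seed)
  causal <- intersect(truth$causal_gene_ids, universe)
  if (direction != "both" && length(truth$causal_gene_signs)) {
    want <- if (direction == "hyper") 1 else -1
    causal <- intersect(causal,
                        names(truth$causal_gene_signs)[
                          truth$causal_gene_signs == want])
  }
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  size_cand <- seq(set_size_range[1], set_size_range[2])
  for (i in seq_len(n_sets)) {
    size <- size_cand[sample.int(length(size_cand), 1)]
    size <- min(size, length(universe))
    if (i <= n_enriched && length(causal) > 0) {
      k <- min(length(causal), round(frac_causal_members * size))
      members <- c(sample(causal, k),
                   sample(setdiff(universe, causal), size - k))
    } else {
      members <- sample(universe, size)
    }
    sets[[i]] <- sort(members)
  }
  enriched <- if (n_enriched > 0) names(sets)[seq_len(n_enriched)]
              else character(0)
  truth$enriched_set_ids <- enriched
  attr(sets, "truth") <- truth
  attr(sets, "enriched_set_ids") <- enriched
  sets
}
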