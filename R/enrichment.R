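#' Build a ranked gene list from promoter-level differential results
#'
#' Maps promoter results to genes (taking the entry with the largest
#' absolute z when a gene has several promoters), and orders genes by the
#' signed z-score, descending. Ties in z are broken by absolute effect
#' size, then lexicographic gene id, so rankings are reproducible.
#'
#' @param promoter_results `meth_diff` tibble on promoters.
#' @param gene_map named character vector promoter_id -> gene_id (e.g. the
#'   `gene_id` attribute of [aggregate_promoters()]).
#' @return tibble of class `ranked_list` with `gene_id` and `stat`, sorted.
#' @export
build_ranked_list <- function(promoter_results, gene_map) {
  res <- promoter_results |>
    dplyr::mutate(gene_id = unname(gene_map[.data$feature_id])) |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_max(abs(.data$z), n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$z), dplyr::desc(abs(.data$effect)),
                   .data$gene_id) |>
    dplyr::select("gene_id", stat = "z")
  if (anyDuplicated(res$gene_id)) stop("duplicate genes in ranked list")
  class(res) <- c("ranked_list", class(res))
  res
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks down the ranked list; positions in the gene set increment the
#' running sum by `|stat|^exponent / sum(|stat in set|^exponent)`, others
#' decrement by `1 / (N - |S|)`. The enrichment score is the running-sum
#' value of largest magnitude.
#'
#' @param ranked `ranked_list` tibble (or any tibble with `gene_id`,
#'   `stat`, already sorted).
#' @param gene_set character vector of gene ids.
#' @param exponent weighting exponent (default 1).
#' @return list with `es` and the `running` sum profile.
#' @export
enrichment_score <- function(ranked, gene_set, exponent = 1) {
  hit <- ranked$gene_id %in% gene_set
  if (!any(hit)) stop("gene set does not intersect the ranked universe",
                      call. = FALSE)
  w <- abs(ranked$stat)^exponent
  if (sum(w[hit]) == 0) stop("all ranking statistics in the set are zero",
                             call. = FALSE)
  N <- nrow(ranked)
  nh <- sum(hit)
  if (N == nh) stop("gene set covers the whole universe", call. = FALSE)
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (N - nh))
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Gene-resampling permutation p-value and normalized enrichment score
#'
#' Draws `n_perm` random gene sets of the same size from the ranked
#' universe, computes their enrichment scores, and returns the one-tailed
#' plus-one permutation p on the observed score's sign together with the
#' normalized score `NES = ES / mean(|null ES| of matching sign)`.
#'
#' @param ranked `ranked_list` tibble.
#' @param gene_set character vector of gene ids.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param exponent weighting exponent.
#' @return list with `p`, `nes`, `es`, `n_perm_used`.
#' @export
gene_permutation_p <- function(ranked, gene_set, n_perm = 10000, seed = 1L,
                               exponent = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  obs <- enrichment_score(ranked, gene_set, exponent)$es
  size <- sum(ranked$gene_id %in% gene_set)
  N <- nrow(ranked)
  set.seed(seed)
  w <- abs(ranked$stat)^exponent
  null_es <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(N, size)
    hit <- logical(N); hit[idx] <- TRUE
    inc <- ifelse(hit, w / sum(w[hit]), -1 / (N - size))
    running <- cumsum(inc)
    running[which.max(abs(running))]
  }, numeric(1))
  same <- null_es * sign(obs) > 0
  if (!any(same)) {
    warning("no matching-sign null scores; using |null| for normalization",
            call. = FALSE)
    denom <- mean(abs(null_es))
    p <- (1 + sum(abs(null_es) >= abs(obs))) / (1 + n_perm)
  } else {
    # one-tailed on the observed sign: both the exceedance count and the
    # denominator run over the same-sign null draws, so null p-values are
    # uniform rather than capped at the sign frequency
    denom <- mean(abs(null_es[same]))
    p <- (1 + sum(same & abs(null_es) >= abs(obs))) / (1 + sum(same))
  }
  list(p = p, nes = obs / denom, es = obs, n_perm_used = n_perm)
}

#' Outcome-label permutation null for gene-set enrichment
#'
#' Builds the empirical null the way the study's validation did: shuffle
#' the treatment labels across individuals (all other covariates stay with
#' their samples), re-run the linear-model fitting, empirical-Bayes
#' moderation, z-ranking and enrichment scoring, and report per set the
#' plus-one fraction of same-sign permutations whose enrichment score is at
#' least as extreme as the observed one (one-sided, conditioned on the
#' observed sign so null p-values are uniform; set `two_sided = TRUE` for a
#' sign-free comparison over all permutations).
#'
#' @param beta promoter (or probe) x samples matrix.
#' @param sheet sample sheet (single-time-point design).
#' @param gene_map promoter -> gene map.
#' @param gene_sets named list of gene-id vectors.
#' @param n_perm number of label permutations (default 500).
#' @param seed integer seed.
#' @param adjust covariates for [build_design()].
#' @param exponent weighting exponent.
#' @param two_sided compare |ES| instead of sign-matched ES.
#' @return tibble with `set_id`, observed `es`, `p_labelperm`,
#'   `n_perm_used`.
#' @export
label_permutation_null <- function(beta, sheet, gene_map, gene_sets,
                                   n_perm = 500, seed = 1L,
                                   adjust = character(), exponent = 1,
                                   two_sided = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  score_once <- function(sh) {
    design <- build_design(sh, mode = "single", adjust = adjust)
    fits <- fit_feature_models(beta, design)
    res <- ebayes_moderate(fits)
    ranked <- build_ranked_list(res, gene_map)
    vapply(gene_sets, function(s) enrichment_score(ranked, s, exponent)$es,
           numeric(1))
  }
  obs <- score_once(sheet)
  set.seed(seed)
  labels <- sheet$treated
  exceed <- numeric(length(gene_sets))
  n_same <- numeric(length(gene_sets))
  for (b in seq_len(n_perm)) {
    repeat {
      perm <- sample(labels)
      if (any(perm) && !all(perm)) break  # degenerate all-one-label: resample
    }
    sh <- sheet
    sh$treated <- perm
    es_b <- score_once(sh)
    same_b <- es_b * sign(obs) > 0
    n_same <- n_same + same_b
    exceed <- exceed + if (two_sided) abs(es_b) >= abs(obs)
                       else same_b & (abs(es_b) >= abs(obs))
  }
  # one-sided p conditions on the same-sign permutations (as in the
  # gene-resampling null) so that null p-values are uniform rather than
  # anti-conservative; the two-sided toggle uses all permutations
  denom <- if (two_sided) rep(n_perm, length(gene_sets)) else n_same
  tibble::tibble(set_id = names(gene_sets), es = unname(obs),
                 p_labelperm = unname((1 + exceed) / (1 + denom)),
                 n_same = unname(n_same),
                 n_perm_used = n_perm)
}

#' Pre-ranked gene-set enrichment over a collection
#'
#' Filters sets to the size window after intersecting with the ranked
#' universe, computes enrichment scores, gene-permutation p-values and
#' normalized scores, and returns a table sorted by p with activation
#' direction, plus a dot-plot-ready top-k summary.
#'
#' @param promoter_results `meth_diff` tibble on promoters.
#' @param gene_sets named list of gene-id vectors (GMT collection).
#' @param gene_map promoter -> gene map.
#' @param n_perm gene permutations per set.
#' @param seed integer seed.
#' @param exponent weighting exponent.
#' @param min_size,max_size gene-set size window (defaults 10, 500).
#' @param top_k sets per direction in the summary.
#' @return tibble of class `meth_gsea`: `set_id`, `size`, `es`, `nes`,
#'   `p_geneperm`, `direction`; attribute `summary` with the top-k table
#'   and `ranked` with the ranked list.
#' @export
run_gsea <- function(promoter_results, gene_sets, gene_map, n_perm = 10000,
                     seed = 1L, exponent = 1, min_size = 10, max_size = 500,
                     top_k = 5) {
  ranked <- build_ranked_list(promoter_results, gene_map)
  sizes <- vapply(gene_sets, function(s) sum(ranked$gene_id %in% s),
                  numeric(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) stop("all gene sets filtered out by the size window",
                       call. = FALSE)
  gene_sets <- gene_sets[keep]
  sizes <- sizes[keep]
  rows <- purrr::imap(gene_sets, function(s, nm) {
    gp <- gene_permutation_p(ranked, s, n_perm = n_perm,
                             seed = seed + match(nm, names(gene_sets)),
                             exponent = exponent)
    tibble::tibble(set_id = nm, size = sizes[[nm]], es = gp$es, nes = gp$nes,
                   p_geneperm = gp$p, n_perm_used = gp$n_perm_used)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(direction = ifelse(.data$es >= 0, "activated",
                                     "suppressed")) |>
    dplyr::arrange(.data$p_geneperm, dplyr::desc(abs(.data$nes)))
  summary_tbl <- out |>
    dplyr::group_by(.data$direction) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::ungroup()
  class(out) <- c("meth_gsea", class(out))
  attr(out, "summary") <- summary_tbl
  attr(out, "ranked") <- ranked
  out
}
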