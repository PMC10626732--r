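fixed_ranked <- function(n = 20, seed = 1) {
  set.seed(seed)
  tibble::tibble(gene_id = paste0("g", sprintf("%02d", seq_len(n))),
                 stat = sort(rnorm(n), decreasing = TRUE))
}


test_that("enrichment score: analytic cases and sign convention", {
  r <- tibble::tibble(gene_id = c("a", "b", "c", "d"), stat = c(4, 3, 2, 1))
  out <- enrichment_score(r, "a")
  expect_equal(out$es, 1)
  expect_equal(out$running[1], 1)
  rneg <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                         stat = c(4, 3, -2, -5))
  expect_lt(enrichment_score(rneg, c("c", "d"))$es, 0)
  expect_error(enrichment_score(r, "zzz"), "does not intersect")
  r0 <- tibble::tibble(gene_id = c("a", "b"), stat = c(0, 1))
  expect_error(enrichment_score(r0, "a"), "zero")
})

test_that("enrichment score matches brute-force and fgsea oracles", {
  skip_if_not_installed("fgsea")
  ranked <- fixed_ranked(20, seed = 3)
  set.seed(4)
  for (rep in 1:5) {
    gs <- sample(ranked$gene_id, 5)
    hit <- ranked$gene_id %in% gs
    mine <- enrichment_score(ranked, gs)$es
    expect_equal(mine, es_oracle(ranked$stat, hit), tolerance = 1e-10)
    fg <- fgsea::calcGseaStat(
      stats = stats::setNames(ranked$stat, ranked$gene_id),
      selectedStats = which(hit), gseaParam = 1)
    expect_equal(mine, fg, tolerance = 1e-10)
  }
})

test_that("reversing the list and negating statistics negates the score", {
  ranked <- fixed_ranked(30, seed = 5)
  set.seed(6)
  gs <- sample(ranked$gene_id, 8)
  es1 <- enrichment_score(ranked, gs)$es
  flipped <- tibble::tibble(gene_id = rev(ranked$gene_id),
                            stat = rev(-ranked$stat))
  es2 <- enrichment_score(flipped, gs)$es
  expect_equal(es2, -es1, tolerance = 1e-12)
  expect_true(abs(es1) <= 1)
})

test_that("gene-permutation p: determinism, resolution floor, plus-one bound", {
  ranked <- fixed_ranked(60, seed = 7)
  gs <- ranked$gene_id[1:12]          # top block: extreme enrichment
  a <- gene_permutation_p(ranked, gs, n_perm = 400, seed = 11)
  b <- gene_permutation_p(ranked, gs, n_perm = 400, seed = 11)
  expect_identical(a, b)
  # resolution floor: no same-sign null draw beats a top-block set, so the
  # plus-one estimate is at its smallest attainable value for this seed
  expect_lte(a$p, 1 / 100)
  expect_gte(a$p, 1 / 401)
  expect_gt(a$nes, 1)
  expect_error(gene_permutation_p(ranked, gs, n_perm = 50), ">= 100")
})

test_that("gene-permutation p-values are approximately uniform on random sets", {
  co <- small_cohort(seed = 71, n_probes = 1000, n_pairs = 0, n_treated = 40,
                     n_untreated = 40, frac_causal_probes = 0,
                     missing_frac = 0)
  sheet <- dplyr::filter(co$sheet, arm == "single")
  regions <- build_region_map(co$annotation)
  prom <- aggregate_promoters(co$beta[, sheet$sample_id], regions)
  d <- build_design(sheet, "single")
  res <- ebayes_moderate(fit_feature_models(prom, d))
  ranked <- build_ranked_list(res, attr(prom, "gene_id"))
  set.seed(72)
  ps <- vapply(1:60, function(i) {
    gs <- sample(ranked$gene_id, 15)
    gene_permutation_p(ranked, gs, n_perm = 200, seed = 100 + i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_true(all(ps > 0))
})

test_that("label permutation null: guards, floor under strong signal, null behaviour", {
  co <- small_cohort(seed = 73, n_probes = 600, n_pairs = 0, n_treated = 30,
                     n_untreated = 30, frac_causal_probes = 0.1,
                     effect_size_delta = 0.25, missing_frac = 0,
                     single_time_override = 0.01)
  sheet <- dplyr::filter(co$sheet, arm == "single")
  regions <- build_region_map(co$annotation)
  prom <- aggregate_promoters(co$beta[, sheet$sample_id], regions)
  gene_map <- attr(prom, "gene_id")
  sets <- make_gene_sets(co$truth, unname(gene_map), n_sets = 6,
                         set_size_range = c(10, 15), n_enriched = 2,
                         direction = "hypo", seed = 74)
  expect_error(label_permutation_null(prom, sheet, gene_map, sets,
                                      n_perm = 0), ">= 1")
  lp <- label_permutation_null(prom, sheet, gene_map, sets, n_perm = 49,
                               seed = 75)
  planted <- attr(sets, "enriched_set_ids")
  pl <- lp[lp$set_id %in% planted, ]
  expect_equal(pl$p_labelperm, 1 / (1 + pl$n_same))   # resolution floor
  expect_true(all(lp$p_labelperm > 0))
})

test_that("label-permutation p is well-behaved on a null cohort", {
  co <- small_cohort(seed = 77, n_probes = 600, n_pairs = 0, n_treated = 25,
                     n_untreated = 25, effect_size_delta = 0,
                     missing_frac = 0)
  sheet <- dplyr::filter(co$sheet, arm == "single")
  regions <- build_region_map(co$annotation)
  prom <- aggregate_promoters(co$beta[, sheet$sample_id], regions)
  gene_map <- attr(prom, "gene_id")
  sets <- make_gene_sets(co$truth, unname(gene_map), n_sets = 10,
                         set_size_range = c(10, 15), n_enriched = 0,
                         seed = 78)
  lp <- label_permutation_null(prom, sheet, gene_map, sets, n_perm = 60,
                               seed = 79)
  expect_gt(median(lp$p_labelperm), 0.1)
})

test_that("run_gsea filters by size, ranks planted suppressed sets on top", {
  co <- small_cohort(seed = 81, n_probes = 1200, n_pairs = 0, n_treated = 50,
                     n_untreated = 50, frac_causal_probes = 0.15,
                     effect_size_delta = 0.3, missing_frac = 0,
                     single_time_override = 0.01)
  sheet <- dplyr::filter(co$sheet, arm == "single")
  regions <- build_region_map(co$annotation)
  prom <- aggregate_promoters(co$beta[, sheet$sample_id], regions)
  gene_map <- attr(prom, "gene_id")
  # force the planted sets towards genes whose planted shift is negative
  truth <- co$truth
  d <- build_design(sheet, "single")
  res <- ebayes_moderate(fit_feature_models(prom, d))
  sets <- make_gene_sets(truth, unname(gene_map), n_sets = 20,
                         set_size_range = c(10, 12), n_enriched = 3,
                         frac_causal_members = 1, direction = "hypo",
                         seed = 82)
  out <- run_gsea(res, sets, gene_map, n_perm = 200, seed = 83)
  expect_s3_class(out, "meth_gsea")
  planted <- attr(sets, "enriched_set_ids")
  expect_lte(max(out$p_geneperm[out$set_id %in% planted]), 1 / 50)
  expect_equal(min(out$p_geneperm), min(out$p_geneperm[out$set_id %in% planted]))
  top3 <- out$set_id[1:3]
  expect_setequal(top3, planted)
  # planted hypomethylation sets occupy the top suppressed ranks
  expect_true(all(out$direction[out$set_id %in% planted] == "suppressed"))
  expect_true(all(out$direction %in% c("activated", "suppressed")))
  expect_identical(out$direction, ifelse(out$es >= 0, "activated",
                                         "suppressed"))
  # size window guard
  expect_error(run_gsea(res, sets, gene_map, min_size = 400,
                        max_size = 500, n_perm = 100), "filtered out")
  # top-k larger than the collection returns everything
  summ <- attr(run_gsea(res, sets, gene_map, n_perm = 100, seed = 1,
                        top_k = 100), "summary")
  expect_equal(nrow(summ), 20)
})
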