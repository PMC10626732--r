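test_that("paired design has the expected structure and contrast", {
  sheet <- toy_paired_sheet(2)
  d <- build_design(sheet, "paired")
  expect_equal(dim(d$X), c(4, 3))
  expect_equal(qr(d$X)$rank, 3)
  expect_equal(sum(d$contrast), 0)
  # contrast recovers the mean within-subject difference exactly
  y <- c(0.2, 0.3, 0.5, 0.8)  # pre1 pre2 post1 post2
  fit <- lm.fit(d$X, y)
  expect_equal(drop(d$contrast %*% fit$coefficients),
               mean(c(0.5 - 0.2, 0.8 - 0.3)))
  expect_error(build_design(sheet[-1, ], "paired"), "paired mode")
})

test_that("single design drops degenerate covariates with a warning", {
  sheet <- tibble::tibble(sample_id = paste0("s", 1:6),
                          subject_id = paste0("s", 1:6),
                          treated = rep(c(TRUE, FALSE), 3),
                          batch = 1L, age = c(50, 60, 55, 58, 62, 49))
  expect_warning(d <- build_design(sheet, "single",
                                   adjust = c("batch", "age")),
                 "single level")
  expect_true("age" %in% colnames(d$X))
  expect_false(any(grepl("batch", colnames(d$X))))
})

test_that("paired contrast is invariant to per-subject constants", {
  co <- small_cohort(seed = 37, n_probes = 300, n_pairs = 10, n_treated = 0,
                     n_untreated = 0, missing_frac = 0)
  sheet <- dplyr::filter(co$sheet, arm == "paired")
  d <- build_design(sheet, "paired")
  beta <- co$beta[, sheet$sample_id]
  f1 <- ebayes_moderate(fit_feature_models(beta, d))
  offs <- stats::setNames(runif(10, -0.05, 0.05), unique(sheet$subject_id))
  beta2 <- beta + matrix(rep(offs[sheet$subject_id], each = nrow(beta)),
                         nrow = nrow(beta))
  f2 <- ebayes_moderate(fit_feature_models(beta2, d))
  expect_equal(f1$effect, f2$effect, tolerance = 1e-10)
})

test_that("per-feature OLS matches lm() coefficient by coefficient", {
  co <- small_cohort(seed = 41, n_probes = 200, n_pairs = 0, n_treated = 12,
                     n_untreated = 10, missing_frac = 0)
  sheet <- dplyr::filter(co$sheet, arm == "single")
  d <- build_design(sheet, "single", adjust = c("age", "ethnicity"))
  beta <- co$beta[1:20, sheet$sample_id]
  fits <- fit_feature_models(beta, d)
  for (i in c(1, 7, 20)) {
    ref <- lm.fit(d$X, beta[i, ])
    expect_equal(unname(fits$coefficients[i, ]), unname(ref$coefficients),
                 tolerance = 1e-10)
    df <- nrow(d$X) - qr(d$X)$rank
    expect_equal(fits$s2[i], sum(ref$residuals^2) / df, tolerance = 1e-10)
  }
  # single-covariate textbook formula
  x <- sheet$age
  y <- beta[3, ]
  b_hat <- cov(x, y) / var(x)
  d2 <- build_design(sheet, "single", adjust = "age")
  f2 <- fit_feature_models(beta, d2)
  # regression of y on (group indicators + age): with balanced groups the
  # age coefficient equals the pooled within-group slope; check against lm
  expect_equal(unname(f2$coefficients[3, "age"]),
               unname(coef(lm(y ~ 0 + factor(sheet$treated) + x))["x"]),
               tolerance = 1e-10)
  expect_true(is.numeric(b_hat))
})

test_that("a feature equal to a design column yields zero residual variance", {
  sheet <- toy_paired_sheet(5)
  d <- build_design(sheet, "paired")
  beta <- rbind(matrix(runif(10 * 10), 10, 10), d$X[, 1])
  rownames(beta) <- paste0("f", 1:11)
  colnames(beta) <- sheet$sample_id
  fits <- fit_feature_models(beta, d)
  expect_lt(fits$s2[11], 1e-20)
})

test_that("empirical-Bayes moderation agrees with the limma oracle", {
  skip_if_not_installed("limma")
  co <- small_cohort(seed = 43, n_probes = 400, n_pairs = 12, n_treated = 0,
                     n_untreated = 0, missing_frac = 0)
  sheet <- dplyr::filter(co$sheet, arm == "paired")
  d <- build_design(sheet, "paired")
  beta <- co$beta[, sheet$sample_id]
  mine <- ebayes_moderate(fit_feature_models(beta, d))
  lf <- limma::lmFit(beta, d$X)
  cf <- limma::contrasts.fit(lf, d$contrast)
  eb <- limma::eBayes(cf)
  expect_equal(mine$effect, unname(eb$coefficients[, 1]), tolerance = 1e-10)
  expect_equal(mine$t, unname(eb$t[, 1]), tolerance = 1e-8)
  expect_equal(mine$p, unname(eb$p.value[, 1]), tolerance = 1e-8)
  expect_equal(attr(mine, "d0"), eb$df.prior, tolerance = 1e-6)
  expect_equal(attr(mine, "s0_2"), eb$s2.prior, tolerance = 1e-6)
  # reported stderr follows the posterior-variance convention
  expect_equal(mine$stderr, unname(eb$stdev.unscaled[, 1]) *
                 sqrt(unname(eb$s2.post)), tolerance = 1e-10)
})

test_that("moderation limits: homogeneous variances and forced infinite prior", {
  set.seed(3)
  X <- cbind(1, rep(0:1, each = 10))
  colnames(X) <- c("b0", "b1")
  d <- structure(list(X = X, contrast = c(b0 = 0, b1 = 1),
                      sample_id = paste0("s", 1:20), mode = "single"),
                 class = "meth_design")
  beta <- matrix(rnorm(40 * 20), 40, 20,
                 dimnames = list(paste0("f", 1:40), paste0("s", 1:20)))
  fits <- fit_feature_models(beta, d)
  # force identical residual variances: scale each row's residuals
  fitted <- fits$coefficients %*% t(X)
  resid <- beta - fitted
  resid_std <- resid / sqrt(fits$s2)
  beta2 <- fitted + resid_std * 0.5
  dimnames(beta2) <- dimnames(beta)
  f2 <- fit_feature_models(beta2, d)
  expect_equal(unname(f2$s2), rep(0.25, 40), tolerance = 1e-12)
  m2 <- ebayes_moderate(f2)
  ord_t <- f2$coefficients %*% d$contrast /
    sqrt(f2$s2 * drop(t(d$contrast) %*% f2$xtx_inv %*% d$contrast))
  expect_equal(m2$t, unname(drop(ord_t)), tolerance = 1e-8)
  expect_equal(attr(m2, "d0"), Inf)
  expect_equal(unique(round(m2$s2_post, 12)), 0.25)
})

test_that("moderated p-values are uniform under the null", {
  co <- small_cohort(seed = 47, n_probes = 200, n_pairs = 30, n_treated = 0,
                     n_untreated = 0, effect_size_delta = 0,
                     missing_frac = 0)
  sheet <- dplyr::filter(co$sheet, arm == "paired")
  d <- build_design(sheet, "paired")
  res <- ebayes_moderate(fit_feature_models(co$beta[, sheet$sample_id], d))
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("Bonferroni thresholds reproduce the published cutoffs", {
  expect_equal(signif(bonferroni_threshold(588798), 3), 8.49e-8)
  expect_equal(signif(bonferroni_threshold(41207), 3), 1.21e-6)
  expect_equal(signif(bonferroni_threshold(525100), 3), 9.52e-8)
  expect_equal(signif(bonferroni_threshold(40271), 3), 1.24e-6)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_error(bonferroni_threshold(0))
})

test_that("promoter aggregation means probes and commutes with subsetting", {
  regions <- tibble::tibble(promoter_id = c("pr1", "pr2", "pr2"),
                            probe_id = c("a", "b", "c"),
                            gene_id = c("g1", "g2", "g2"))
  beta <- rbind(a = c(0.1, 0.9), b = c(0.2, 0.6), c = c(0.4, 0.8))
  colnames(beta) <- c("s1", "s2")
  agg <- aggregate_promoters(beta, regions)
  expect_equal(agg["pr1", ], beta["a", ])           # single-probe promoter
  expect_equal(unname(agg["pr2", ]), c(0.3, 0.7))
  # commutes with sample subsetting
  agg_sub <- aggregate_promoters(beta[, "s2", drop = FALSE], regions)
  expect_equal(agg_sub[, "s2"], agg[, "s2"])
  expect_identical(attr(agg, "gene_id"),
                   c(pr1 = "g1", pr2 = "g2"))
})

test_that("significance calling and sign-aware intersection", {
  mk <- function(ids, p, eff) {
    r <- tibble::tibble(feature_id = ids, effect = eff, p = p)
    class(r) <- c("meth_diff", class(r))
    call_significant(r, 0.05)
  }
  r1 <- mk(c("a", "b"), c(0.01, 0.5), c(1, 1))
  r2 <- mk(c("a", "b"), c(0.02, 0.01), c(1, -1))
  r3 <- mk(c("a", "b"), c(0.6, 0.7), c(1, 1))
  expect_identical(intersect_significant(list(r1, r2)), "a")
  expect_identical(intersect_significant(list(r1, r2, r3)), character(0))
  r4 <- mk("a", 0.01, -1)
  expect_identical(intersect_significant(list(r1, r4)), character(0))
})

test_that("shared planted effects survive intersection across three datasets", {
  # one truth, three datasets: the paired arm and two halves of the
  # single-time-point arm (all samples taken shortly after treatment so the
  # planted shift is undecayed)
  co <- small_cohort(seed = 61, n_probes = 400, n_pairs = 40, n_treated = 80,
                     n_untreated = 80, frac_causal_probes = 0.05,
                     effect_size_delta = 0.15, missing_frac = 0,
                     single_time_override = 0.05)
  thr <- bonferroni_threshold(400)
  paired <- dplyr::filter(co$sheet, arm == "paired")
  dp <- build_design(paired, "paired")
  r1 <- call_significant(
    ebayes_moderate(fit_feature_models(co$beta[, paired$sample_id], dp)), thr)
  single <- dplyr::filter(co$sheet, arm == "single")
  set.seed(1)
  half <- sample(c(TRUE, FALSE), nrow(single), replace = TRUE)
  mk_single <- function(sh) {
    d <- build_design(sh, "single")
    call_significant(
      ebayes_moderate(fit_feature_models(co$beta[, sh$sample_id], d)), thr)
  }
  r2 <- mk_single(single[half, ])
  r3 <- mk_single(single[!half, ])
  strong <- names(which(abs(co$truth$true_delta_per_probe) >= 0.15))
  hits <- intersect_significant(list(r1, r2, r3))
  expect_gt(length(strong), 0)
  expect_true(all(strong %in% hits))
  # and the effect signs recovered agree with the planted signs
  sgn <- sign(co$truth$true_delta_per_probe[strong])
  expect_equal(unname(sign(r1$effect[match(strong, r1$feature_id)])),
               unname(sgn))
})
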