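#' Build a design matrix for paired or single-time-point analysis
#'
#' Paired mode uses an intercept-free time factor plus subject indicator
#' blocks (`~ 0 + time + subject`), the contrast being post minus pre;
#' single mode uses an intercept-free treatment factor plus the requested
#' adjustment covariates, the contrast being treated minus untreated.
#' Categorical covariates are expanded to indicators against a documented
#' reference level (earliest batch, majority ethnicity); covariates that
#' are constant are dropped with a warning.
#'
#' @param sheet sample sheet tibble with `sample_id`, `subject_id`,
#'   `timepoint` (paired) or `treated` (single), and any covariates named
#'   in `adjust`.
#' @param mode `"paired"` or `"single"`.
#' @param adjust character vector of covariate column names in `sheet`
#'   (numeric kept as-is, character/factor expanded to indicators).
#' @return object of class `meth_design`: list with the model matrix `X`
#'   (rows in `sheet` order), `contrast` vector, and `sample_id`.
#' @export
build_design <- function(sheet, mode = c("paired", "single"),
                         adjust = character()) {
  mode <- match.arg(mode)
  stopifnot(all(adjust %in% names(sheet)))
  if (mode == "paired") {
    tab <- table(sheet$subject_id, sheet$timepoint)
    ok <- nrow(tab) > 0 && all(tab == 1) &&
      setequal(colnames(tab), c("pre", "post"))
    if (!ok)
      stop("paired mode requires exactly one pre and one post sample per subject",
           call. = FALSE)
    time <- factor(sheet$timepoint, levels = c("pre", "post"))
    subj <- factor(sheet$subject_id)
    X <- stats::model.matrix(~ 0 + time + subj)
    contrast <- stats::setNames(rep(0, ncol(X)), colnames(X))
    contrast["timepost"] <- 1
    contrast["timepre"] <- -1
  } else {
    tr <- factor(ifelse(sheet$treated, "treated", "untreated"),
                 levels = c("untreated", "treated"))
    if (nlevels(droplevels(tr)) < 2)
      stop("single mode needs both treated and untreated samples",
           call. = FALSE)
    X <- stats::model.matrix(~ 0 + tr)
    colnames(X) <- c("untreated", "treated")
    contrast <- stats::setNames(c(-1, 1), colnames(X))
  }
  for (cv in adjust) {
    v <- sheet[[cv]]
    if (cv == "batch") v <- factor(v)   # batches are categorical even if coded 1..k
    if (is.numeric(v)) {
      if (stats::sd(v) == 0) {
        warning("covariate '", cv, "' is constant; dropped", call. = FALSE)
        next
      }
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- cv
      contrast <- c(contrast, stats::setNames(0, cv))
    } else {
      f <- factor(v)
      # reference level: earliest batch / majority class
      ref <- if (cv == "batch") levels(f)[1]
             else names(sort(table(f), decreasing = TRUE))[1]
      f <- stats::relevel(f, ref)
      if (nlevels(droplevels(f)) < 2) {
        warning("covariate '", cv, "' has a single level; dropped",
                call. = FALSE)
        next
      }
      mm <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, sub("^f", "_", colnames(mm)))
      X <- cbind(X, mm)
      contrast <- c(contrast, stats::setNames(rep(0, ncol(mm)), colnames(mm)))
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    # subject blocks are expected to absorb one time column's worth of rank
    stop("design matrix is collinear; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(X = X, contrast = contrast, sample_id = sheet$sample_id,
                 mode = mode),
            class = "meth_design")
}

#' Per-feature ordinary least squares fits
#'
#' Fits the same linear model to every feature (row) of the beta matrix by
#' ordinary least squares, returning the full coefficient matrix together
#' with the residual variance, residual degrees of freedom, and the
#' unscaled covariance factor needed for contrast standard errors.
#'
#' @param beta features x samples matrix, complete; columns must match the
#'   design's samples (they are reordered by sample id).
#' @param design a `meth_design` from [build_design()].
#' @return object of class `meth_fit`: list with `coefficients`
#'   (features x p), `s2`, `df_residual`, `xtx_inv`, `design`.
#' @export
fit_feature_models <- function(beta, design) {
  stopifnot(inherits(design, "meth_design"))
  if (!all(design$sample_id %in% colnames(beta)))
    stop("beta matrix lacks samples required by the design", call. = FALSE)
  Y <- beta[, design$sample_id, drop = FALSE]
  if (anyNA(Y)) stop("beta matrix must be complete", call. = FALSE)
  X <- design$X
  n <- nrow(X)
  r <- qr(X)$rank
  if (n <= r) stop("zero residual degrees of freedom", call. = FALSE)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  B <- Y %*% X %*% xtx_inv            # features x p
  colnames(B) <- colnames(X)
  resid <- Y - B %*% t(X)
  df <- n - r
  s2 <- unname(rowSums(resid^2) / df)
  structure(list(coefficients = B, s2 = s2, df_residual = df,
                 xtx_inv = xtx_inv, design = design,
                 feature_id = rownames(Y)),
            class = "meth_fit")
}

# Newton solver for trigamma(x) = y
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2)
      x <- x + dif
      if (-dif / x < 1e-8) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of per-feature variances and contrast tests
#'
#' Estimates a prior on the residual variances by moment matching on the
#' log variances (Fisher digamma/trigamma equations), forms the posterior
#' variance `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)`, and returns the
#' moderated t-statistic, two-sided p-value and signed z-score for the
#' requested contrast. Features with zero residual variance are excluded
#' from prior estimation and assigned the prior variance.
#'
#' @param fits a `meth_fit` object.
#' @param contrast optional numeric contrast vector (defaults to the
#'   design's contrast).
#' @return tibble of class `meth_diff` with columns `feature_id`, `effect`,
#'   `stderr`, `t`, `df_total`, `p`, `z`, `s2_post`; attributes `d0`, `s0_2`.
#' @export
ebayes_moderate <- function(fits, contrast = NULL) {
  stopifnot(inherits(fits, "meth_fit"))
  if (is.null(contrast)) contrast <- fits$design$contrast
  stopifnot(length(contrast) == ncol(fits$coefficients))
  if (length(fits$s2) < 10)
    stop("need at least 10 features to estimate the variance prior",
         call. = FALSE)
  effect <- unname(drop(fits$coefficients %*% contrast))
  unscaled <- sqrt(drop(t(contrast) %*% fits$xtx_inv %*% contrast))
  df <- fits$df_residual
  s2 <- fits$s2
  pos <- s2 > 0
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(emean) || !is.finite(evar)) {
    warning("non-finite prior moment estimates; falling back to unmoderated t",
            call. = FALSE)
    d0 <- 0; s0_2 <- NA_real_
    s2_post <- s2
  } else if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
    s2_post[!pos] <- s0_2 * d0 / (d0 + df) # zero-variance features shrink to prior
  } else {
    # no excess dispersion in the log variances: infinite prior df, prior
    # variance equal to the average observed variance
    d0 <- Inf
    s0_2 <- mean(s2[pos])
    s2_post <- rep(s0_2, length(s2))
  }
  df_total <- df + d0
  tstat <- effect / (unscaled * sqrt(s2_post))
  p <- if (is.finite(d0)) 2 * stats::pt(-abs(tstat), df_total)
       else 2 * stats::pnorm(-abs(tstat))
  p <- pmax(p, .Machine$double.xmin)
  out <- tibble::tibble(
    feature_id = fits$feature_id,
    effect = effect,
    stderr = unscaled * sqrt(s2_post),
    t = tstat,
    df_total = df_total,
    p = p,
    z = p_to_z(p, effect),
    s2_post = s2_post)
  class(out) <- c("meth_diff", class(out))
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

#' Bonferroni family-wise significance threshold
#'
#' @param n_tests number of tests.
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Build a promoter region map from probe annotation
#'
#' @param annotation probe annotation tibble with `probe_id`,
#'   `promoter_id`, `gene_id`.
#' @return tibble with one row per promoter member probe.
#' @export
build_region_map <- function(annotation) {
  annotation |>
    dplyr::filter(!is.na(.data$promoter_id)) |>
    dplyr::select("promoter_id", "probe_id", "gene_id") |>
    dplyr::arrange(.data$promoter_id, .data$probe_id)
}

#' Assign probes to promoters from transcription start sites
#'
#' Promoters are the windows 1.5 kb upstream to 0.5 kb downstream of each
#' TSS (strand-aware); a probe belongs to a promoter when its position
#' falls in the half-open window.
#'
#' @param annotation probe annotation with `probe_id`, `chrom`, `position`.
#' @param tss tibble with `gene_id`, `chrom`, `tss`, `strand` (`"+"`/`"-"`).
#' @param upstream,downstream window extents in bp.
#' @return region map tibble (`promoter_id`, `probe_id`, `gene_id`).
#' @export
region_map_from_tss <- function(annotation, tss, upstream = 1500,
                                downstream = 500) {
  tss <- tss |>
    dplyr::mutate(
      start = ifelse(.data$strand == "+", .data$tss - upstream,
                     .data$tss - downstream),
      end = ifelse(.data$strand == "+", .data$tss + downstream,
                   .data$tss + upstream),
      promoter_id = paste0("prom_", .data$gene_id))
  dplyr::inner_join(annotation, tss, by = "chrom",
                    relationship = "many-to-many") |>
    dplyr::filter(.data$position >= .data$start,
                  .data$position < .data$end) |>
    dplyr::select("promoter_id", "probe_id", "gene_id")
}

#' Aggregate probe betas to promoter-level betas
#'
#' Promoter value is the arithmetic mean of its member probes per sample;
#' promoters with no retained probes are dropped and recorded in the
#' `dropped` attribute.
#'
#' @param beta probes x samples matrix.
#' @param regions region map tibble from [build_region_map()].
#' @return promoters x samples matrix with attribute `gene_id` (named map
#'   promoter -> gene) and `dropped`.
#' @export
aggregate_promoters <- function(beta, regions) {
  regions <- regions[regions$probe_id %in% rownames(beta), ]
  if (nrow(regions) == 0)
    stop("no promoter probes retained in the matrix", call. = FALSE)
  all_proms <- unique(regions$promoter_id)
  grp <- factor(regions$promoter_id, levels = all_proms)
  sums <- rowsum(beta[regions$probe_id, , drop = FALSE], grp)
  counts <- as.vector(table(grp))
  out <- sums / counts
  gene_map <- regions |>
    dplyr::distinct(.data$promoter_id, .data$gene_id)
  attr(out, "gene_id") <- stats::setNames(gene_map$gene_id,
                                          gene_map$promoter_id)
  attr(out, "dropped") <- character(0)
  out
}

#' Flag significant features and intersect across datasets
#'
#' `call_significant()` flags features with `p < threshold`.
#' `intersect_significant()` returns features significant with
#' sign-concordant effects in every supplied result set.
#'
#' @param results a `meth_diff` tibble.
#' @param threshold p-value cutoff, typically from
#'   [bonferroni_threshold()].
#' @return the tibble with a `significant` column; attribute `n_significant`.
#' @export
call_significant <- function(results, threshold) {
  results$significant <- results$p < threshold
  attr(results, "threshold") <- threshold
  attr(results, "n_significant") <- sum(results$significant)
  results
}

#' @rdname call_significant
#' @param result_list list of flagged `meth_diff` tibbles (after
#'   [call_significant()]).
#' @return for `intersect_significant()`: character vector of feature ids
#'   significant, with identical effect sign, in all result sets.
#' @export
intersect_significant <- function(result_list) {
  sig <- lapply(result_list, function(r) r$feature_id[r$significant])
  common <- Reduce(intersect, sig)
  if (!length(common)) return(character(0))
  signs <- vapply(result_list, function(r)
    sign(r$effect[match(common, r$feature_id)]), numeric(length(common)))
  signs <- matrix(signs, nrow = length(common))
  keep <- apply(signs, 1, function(s) all(s == s[1]) && all(s != 0))
  common[keep]
}
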