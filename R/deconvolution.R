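#' Reference-based cell-fraction inference by robust partial correlations
#'
#' For every sample, regresses its beta values at the reference marker
#' probes on the reference cell-type profiles by robust (Huber) linear
#' regression, truncates negative coefficients at zero and rescales the
#' rest to sum to one. This is the RPC estimator family used for blood
#' deconvolution against type-specific marker references; the closure to
#' the simplex is this package's convention so the fractions are directly
#' usable as model covariates.
#'
#' @param beta probes x samples matrix (post-QC).
#' @param reference marker probes x cell types beta matrix with rownames
#'   matching probe ids.
#' @param min_marker_frac minimum fraction of reference markers that must
#'   survive QC (default 0.8).
#' @param maxit,k Huber IRLS iteration cap and tuning constant.
#' @return tibble with `sample_id` and one column per cell type; attribute
#'   `method = "RPC"`.
#' @export
rpc_fractions <- function(beta, reference, min_marker_frac = 0.8,
                          maxit = 100, k = 1.345) {
  common <- intersect(rownames(reference), rownames(beta))
  if (length(common) < min_marker_frac * nrow(reference))
    stop(sprintf("only %d/%d reference marker probes present (need >= %.0f%%)",
                 length(common), nrow(reference), 100 * min_marker_frac),
         call. = FALSE)
  X <- reference[common, , drop = FALSE]
  if (qr(X)$rank < ncol(X))
    stop("reference methylome is rank-deficient", call. = FALSE)
  Y <- beta[common, , drop = FALSE]
  Xi <- cbind(`(Intercept)` = 1, X)
  est <- vapply(seq_len(ncol(Y)), function(j) {
    fit <- MASS::rlm(Xi, Y[, j], maxit = maxit, k = k)
    co <- pmax(fit$coefficients[-1], 0)
    if (sum(co) == 0) co else co / sum(co)
  }, numeric(ncol(X)))
  out <- tibble::as_tibble(t(est))
  names(out) <- colnames(X)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(Y)), out)
  attr(out, "method") <- "RPC"
  out
}

#' LUMP-style immune-content score
#'
#' Leukocytes-unmethylation-for-purity: averages `1 - beta` over a panel
#' of probes unmethylated in leukocytes, divides by the 0.85 reference
#' scale and caps at 1, giving a per-sample immune-cell-content score in
#' `[0, 1]`.
#'
#' @param beta probes x samples matrix.
#' @param lump_probes character vector of panel probe ids.
#' @param scale reference unmethylation level of a pure leukocyte sample.
#' @return tibble with `sample_id` and `lump`; attribute `probes_used`.
#' @export
lump_score <- function(beta, lump_probes, scale = 0.85) {
  probes <- intersect(lump_probes, rownames(beta))
  if (!length(probes))
    stop("no LUMP panel probes present in the matrix", call. = FALSE)
  score <- pmin(1, colMeans(1 - beta[probes, , drop = FALSE], na.rm = TRUE) /
                  scale)
  out <- tibble::tibble(sample_id = colnames(beta), lump = unname(score))
  attr(out, "probes_used") <- probes
  out
}

#' Sample purity filter on immune-content scores
#'
#' Retains samples whose LUMP score is at least `min_score` (default 0.9);
#' samples strictly below the cutoff are logged for the QC report.
#'
#' @param scores tibble from [lump_score()].
#' @param min_score purity cutoff.
#' @return list with `samples` (retained ids) and `report` tibble.
#' @export
purity_filter <- function(scores, min_score = 0.9) {
  keep <- scores$lump >= min_score
  list(samples = scores$sample_id[keep],
       report = tibble::tibble(sample_id = scores$sample_id[!keep],
                               reason = "low_purity",
                               lump = scores$lump[!keep]))
}
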