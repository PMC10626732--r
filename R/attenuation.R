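#' Stratify samples by time since treatment start
#'
#' Treated samples are binned into half-open intervals `[0, 0.5)`,
#' `[0.5, 2)`, `[2, Inf)` years since treatment start; treated samples
#' with missing time are labelled `unspecified`; untreated samples pass
#' through as `untreated`.
#'
#' @param sheet sample sheet with `treated` and `time_from_treatment`
#'   (years).
#' @param cutpoints two increasing cutpoints in years (default 0.5, 2).
#' @return tibble with `sample_id` and `stratum` (factor with levels
#'   untreated, lt_0.5y, 0.5_2y, gt_2y, unspecified).
#' @export
stratify_by_time <- function(sheet, cutpoints = c(0.5, 2)) {
  stopifnot(length(cutpoints) == 2, cutpoints[1] < cutpoints[2])
  t <- sheet$time_from_treatment
  if (any(!is.na(t) & t < 0)) stop("negative times not allowed", call. = FALSE)
  lab <- rep("untreated", nrow(sheet))
  tr <- sheet$treated
  lab[tr & is.na(t)] <- "unspecified"
  ok <- tr & !is.na(t)
  lab[ok & t < cutpoints[1]] <- "lt_0.5y"
  lab[ok & t >= cutpoints[1] & t < cutpoints[2]] <- "0.5_2y"
  lab[ok & t >= cutpoints[2]] <- "gt_2y"
  tibble::tibble(sample_id = sheet$sample_id,
                 stratum = factor(lab, levels = stratum_levels))
}

#' Joint stratified differential models against untreated samples
#'
#' Fits one intercept-free linear model per feature with a five-level
#' time-stratum factor (untreated as the reference) plus the requested
#' covariate adjustment, and extracts each stratum-versus-untreated effect
#' as a contrast from the single joint fit, sharing one empirical-Bayes
#' variance moderation.
#'
#' @param beta features x samples matrix.
#' @param sheet sample sheet.
#' @param strata tibble from [stratify_by_time()].
#' @param adjust covariates for adjustment (as in [build_design()]).
#' @return named list of `meth_diff` tibbles, one per non-empty treated
#'   stratum (`lt_0.5y`, `0.5_2y`, `gt_2y`, `unspecified`), class
#'   `meth_attenuation`.
#' @export
fit_strata_models <- function(beta, sheet, strata, adjust = character()) {
  sh <- sheet |>
    dplyr::select(-dplyr::any_of("stratum")) |>
    dplyr::left_join(strata, by = "sample_id")
  sh$stratum <- droplevels(sh$stratum)
  if (!"untreated" %in% levels(sh$stratum))
    stop("no untreated samples to compare against", call. = FALSE)
  X <- stats::model.matrix(~ 0 + stratum, data = sh)
  colnames(X) <- sub("^stratum", "", colnames(X))
  contrast0 <- stats::setNames(rep(0, ncol(X)), colnames(X))
  design <- structure(list(X = X, contrast = contrast0,
                           sample_id = sh$sample_id, mode = "single"),
                      class = "meth_design")
  # append covariates through the same expansion rules as build_design()
  if (length(adjust)) {
    aug <- build_design(dplyr::mutate(sh, treated = sh$stratum != "untreated"),
                        mode = "single", adjust = adjust)
    extra <- aug$X[, setdiff(colnames(aug$X), c("untreated", "treated")),
                   drop = FALSE]
    design$X <- cbind(X, extra)
    design$contrast <- c(contrast0,
                         stats::setNames(rep(0, ncol(extra)), colnames(extra)))
  }
  fits <- fit_feature_models(beta, design)
  treated_levels <- setdiff(levels(sh$stratum), "untreated")
  out <- lapply(treated_levels, function(lv) {
    if (sum(sh$stratum == lv) == 0) return(NULL)
    ctr <- design$contrast
    ctr[lv] <- 1
    ctr["untreated"] <- -1
    ebayes_moderate(fits, ctr)
  })
  names(out) <- treated_levels
  out <- out[!vapply(out, is.null, logical(1))]
  class(out) <- "meth_attenuation"
  out
}

#' Attenuation slope between two comparisons' effect sizes
#'
#' Regresses the late-comparison effects on the early-comparison effects
#' for the same features, through the origin by default (the hypothesis is
#' proportional attenuation of the same planted effects), returning the
#' slope and its standard error.
#'
#' @param effects_early,effects_late equal-length numeric vectors of
#'   per-feature effects (matched order).
#' @param intercept fit an intercept as well (default FALSE).
#' @return list with `slope`, `stderr`, `n`.
#' @export
attenuation_slope <- function(effects_early, effects_late,
                              intercept = FALSE) {
  stopifnot(length(effects_early) == length(effects_late))
  ok <- is.finite(effects_early) & is.finite(effects_late)
  x <- effects_early[ok]; y <- effects_late[ok]
  if (length(x) < 2 || sum(x^2) < 1e-12 || stats::sd(x) < 1e-10)
    stop("near-zero variance in early effects; slope undefined",
         call. = FALSE)
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ 0 + x)
  # exact proportionality triggers the perfect-fit warning; SE 0 is valid here
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(sm["x", "Estimate"]),
       stderr = unname(sm["x", "Std. Error"]), n = length(x))
}

#' Persistence counts and direction-consistency across time strata
#'
#' Counts significant features per stratum comparison; among the features
#' significant in the latest comparison, flags those whose effects have the
#' same sign in every comparison and those whose absolute effects decrease
#' monotonically from the earliest to the latest comparison.
#'
#' @param strata_results `meth_attenuation` list (ordered early to late;
#'   the `unspecified` stratum is ignored).
#' @param threshold p-value significance cutoff.
#' @return list with `counts` (named per comparison), `consistent_ids`,
#'   `monotone_ids`, and tibble `summary`.
#' @export
count_persistent <- function(strata_results, threshold) {
  res <- strata_results[setdiff(names(strata_results), "unspecified")]
  counts <- vapply(res, function(r) sum(r$p < threshold), numeric(1))
  last <- res[[length(res)]]
  sig_last <- last$feature_id[last$p < threshold]
  eff <- vapply(res, function(r) r$effect[match(sig_last, r$feature_id)],
                numeric(length(sig_last)))
  eff <- matrix(eff, nrow = length(sig_last))
  if (length(sig_last)) {
    consistent <- apply(eff, 1, function(e) all(sign(e) == sign(e[1]),
                                                e[1] != 0))
    monotone <- consistent &
      apply(eff, 1, function(e) all(diff(abs(e)) < 0))
  } else consistent <- monotone <- logical(0)
  list(counts = counts,
       consistent_ids = sig_last[consistent],
       monotone_ids = sig_last[monotone],
       summary = tibble::tibble(
         comparison = names(counts), n_significant = unname(counts),
         n_sig_latest = length(sig_last),
         n_consistent = sum(consistent), n_monotone = sum(monotone)))
}
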