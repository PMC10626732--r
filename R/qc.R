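#' Iterative Greedycut filtering of a detection p-value matrix
#'
#' Repeatedly removes the probe (row) or sample (column) whose fraction of
#' detection p-values above `alpha` is largest, until no entry fails.
#' Ties between the worst row and the worst column are resolved by removing
#' the row; ties within an axis are resolved by original order, so the
#' removal sequence is deterministic.
#'
#' @param detp numeric matrix of detection p-values (probes x samples),
#'   values in `[0, 1]`, with dimnames.
#' @param alpha detection p-value cutoff (default 0.01).
#' @return list with `probes` and `samples` (retained ids) and `report`,
#'   a tibble of removals (`step`, `axis`, `id`, `fail_fraction`).
#' @export
greedycut_filter <- function(detp, alpha = 0.01) {
  if (!is.matrix(detp) || nrow(detp) == 0 || ncol(detp) == 0)
    stop("detection p matrix is empty", call. = FALSE)
  if (any(detp < 0 | detp > 1)) stop("detection p outside [0, 1]", call. = FALSE)
  if (is.null(rownames(detp))) rownames(detp) <- paste0("p", seq_len(nrow(detp)))
  if (is.null(colnames(detp))) colnames(detp) <- paste0("s", seq_len(ncol(detp)))
  fail <- detp > alpha
  removed <- list()
  step <- 0L
  while (any(fail) && nrow(fail) > 1 && ncol(fail) > 1) {
    rf <- rowMeans(fail)
    cf <- colMeans(fail)
    step <- step + 1L
    if (max(rf) >= max(cf)) {
      i <- which.max(rf)
      removed[[step]] <- tibble::tibble(step = step, axis = "probe",
                                        id = rownames(fail)[i],
                                        fail_fraction = rf[[i]])
      fail <- fail[-i, , drop = FALSE]
    } else {
      j <- which.max(cf)
      removed[[step]] <- tibble::tibble(step = step, axis = "sample",
                                        id = colnames(fail)[j],
                                        fail_fraction = cf[[j]])
      fail <- fail[, -j, drop = FALSE]
    }
  }
  report <- if (length(removed)) dplyr::bind_rows(removed)
            else tibble::tibble(step = integer(), axis = character(),
                                id = character(), fail_fraction = numeric())
  list(probes = rownames(fail), samples = colnames(fail), report = report)
}

# ---- three-state beta mixture via EM (moment-matching M-step) -------------

fit_beta_mixture <- function(x, K = 3, max_iter = 200, tol = 1e-6) {
  n <- length(x)
  # initialize at the beta-scale anchors of the three methylation states
  # (unmethylated < 0.3, hemimethylated, methylated > 0.7); a plain
  # quantile split mis-seeds the small middle state on real-shaped data
  comp <- if (K == 3) cut(x, c(0, 0.3, 0.7, 1), labels = FALSE,
                          include.lowest = TRUE)
          else cut(x, stats::quantile(x, seq(0, 1, length.out = K + 1)),
                   labels = FALSE, include.lowest = TRUE)
  if (length(unique(comp)) < K)
    comp <- pmin(K, pmax(1, ceiling(rank(x, ties.method = "first") / n * K)))
  a <- b <- w <- numeric(K)
  for (k in seq_len(K)) {
    xs <- x[comp == k]
    m <- mean(xs); v <- max(stats::var(xs), 1e-8)
    phi <- max(m * (1 - m) / v - 1, 1e-3)
    a[k] <- m * phi; b[k] <- (1 - m) * phi; w[k] <- length(xs) / n
  }
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(K),
                   function(k) w[k] * stats::dbeta(x, a[k], b[k]),
                   numeric(n))
    rs <- rowSums(dens)
    rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    r <- dens / rs
    for (k in seq_len(K)) {
      rk <- r[, k]
      sk <- sum(rk)
      if (sk < 1e-8) next
      m <- sum(rk * x) / sk
      v <- max(sum(rk * (x - m)^2) / sk, 1e-8)
      m <- min(max(m, 1e-4), 1 - 1e-4)
      phi <- max(m * (1 - m) / v - 1, 1e-3)
      a[k] <- m * phi; b[k] <- (1 - m) * phi; w[k] <- sk / n
    }
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE; break
    }
    ll_old <- ll
  }
  means <- a / (a + b)
  ord <- order(means)
  if (min(w) < 1e-4)
    warning("degenerate beta-mixture component (near-zero weight)",
            call. = FALSE)
  list(a = a[ord], b = b[ord], w = w[ord], loglik = ll,
       converged = converged, n_iter = iter)
}

#' BMIQ: beta-mixture quantile normalization of type-II probes
#'
#' Fits a three-state (unmethylated / hemimethylated / methylated) beta
#' mixture separately to the type-I and type-II probes of one sample,
#' quantile-maps the type-II unmethylated and methylated states onto the
#' corresponding type-I mixture components, and linearly interpolates the
#' middle state between the mapped state boundaries. Type-I probes are
#' returned unchanged. If the two design classes' empirical distributions
#' are already statistically indistinguishable (two-sample KS statistic
#' below `identity_ks`, which defaults to the 1%-level KS critical value
#' for the observed class sizes) the transform is the identity, which
#' makes repeated application idempotent.
#'
#' @param beta_sample numeric vector of one sample's beta values.
#' @param design_class character vector (`"I"`/`"II"`) per probe.
#' @param eps clipping bound applied before EM (default 1e-6).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param identity_ks KS-distance threshold under which no correction is
#'   applied; `NULL` (default) uses the 1%-level two-sample KS critical
#'   value `1.63 * sqrt(1/n_I + 1/n_II)`.
#' @return normalized beta vector in `[0, 1]`, same order as input.
#' @export
bmiq_normalize <- function(beta_sample, design_class, eps = 1e-6,
                           max_iter = 200, tol = 1e-6, identity_ks = NULL) {
  stopifnot(length(beta_sample) == length(design_class))
  i1 <- design_class == "I"
  i2 <- design_class == "II"
  if (!any(i1) || !any(i2))
    stop("both design classes must be present", call. = FALSE)
  if (is.null(identity_ks))
    identity_ks <- 1.63 * sqrt(1 / sum(i1) + 1 / sum(i2))
  x <- clip01(beta_sample, eps)
  if (ks_stat(x[i1], x[i2]) < identity_ks) return(beta_sample)
  f1 <- fit_beta_mixture(x[i1], max_iter = max_iter, tol = tol)
  f2 <- fit_beta_mixture(x[i2], max_iter = max_iter, tol = tol)
  if (!f1$converged || !f2$converged)
    warning(sprintf("BMIQ EM did not converge (type I: %d iter, type II: %d iter)",
                    f1$n_iter, f2$n_iter), call. = FALSE)
  x2 <- x[i2]
  dens <- vapply(1:3, function(k) f2$w[k] * stats::dbeta(x2, f2$a[k], f2$b[k]),
                 numeric(length(x2)))
  state <- max.col(dens, ties.method = "first")  # deterministic: no RNG use
  out2 <- x2
  # unmethylated state: map through the U components of both fits
  u <- state == 1
  if (any(u)) {
    p <- stats::pbeta(x2[u], f2$a[1], f2$b[1])
    out2[u] <- stats::qbeta(pmin(pmax(p, eps), 1 - eps), f1$a[1], f1$b[1])
  }
  m <- state == 3
  if (any(m)) {
    p <- stats::pbeta(x2[m], f2$a[3], f2$b[3])
    out2[m] <- stats::qbeta(pmin(pmax(p, eps), 1 - eps), f1$a[3], f1$b[3])
  }
  h <- state == 2
  if (any(h)) {
    lo_src <- if (any(u)) max(x2[u]) else min(x2[h])
    hi_src <- if (any(m)) min(x2[m]) else max(x2[h])
    lo_dst <- if (any(u)) max(out2[u]) else lo_src
    hi_dst <- if (any(m)) min(out2[m]) else hi_src
    if (hi_src <= lo_src || hi_dst <= lo_dst) {
      # degenerate middle state: leave values in place
      warning("BMIQ middle state degenerate; left uncorrected", call. = FALSE)
    } else {
      out2[h] <- lo_dst + (x2[h] - lo_src) / (hi_src - lo_src) *
        (hi_dst - lo_dst)
    }
  }
  out <- beta_sample
  out[i2] <- pmin(pmax(out2, 0), 1)
  out
}

#' Apply BMIQ to every sample of a beta matrix
#'
#' @param beta probes x samples matrix (no missing values among entries
#'   used for mixture fitting; missing entries are passed through).
#' @param annotation probe annotation tibble with `probe_id` and
#'   `design_class`.
#' @param ... passed to [bmiq_normalize()].
#' @return normalized beta matrix.
#' @export
bmiq_normalize_matrix <- function(beta, annotation, ...) {
  dc <- annotation$design_class[match(rownames(beta), annotation$probe_id)]
  out <- beta
  for (j in seq_len(ncol(beta))) {
    obs <- !is.na(beta[, j])
    out[obs, j] <- bmiq_normalize(beta[obs, j], dc[obs], ...)
  }
  out
}

#' Probe filtering on variability, sequence context, and annotation flags
#'
#' Removes probes with standard deviation strictly below `sd_min`
#' (default 0.005), probes in non-CpG sequence contexts, probes flagged as
#' SNP-overlapping or cross-reactive, and chromosome Y probes. Filters have
#' set-intersection semantics: a probe is retained iff it passes every
#' filter, so composition order is irrelevant.
#'
#' @param beta probes x samples matrix (missing values allowed).
#' @param annotation probe annotation tibble.
#' @param sd_min minimum per-probe standard deviation (strict).
#' @param drop_contexts contexts to remove.
#' @param drop_snp,drop_cross,drop_chrY toggle the flag filters.
#' @return list with filtered `beta`, `report` tibble (probe_id, reason)
#'   and `counts` per criterion.
#' @export
filter_probes <- function(beta, annotation, sd_min = 0.005,
                          drop_contexts = c("CC", "CAG", "CAH", "CTG",
                                            "CTH", "Other"),
                          drop_snp = TRUE, drop_cross = TRUE,
                          drop_chrY = TRUE) {
  ann <- annotation[match(rownames(beta), annotation$probe_id), ]
  sds <- apply(beta, 1, stats::sd, na.rm = TRUE)
  low_sd <- !is.na(sds) & sds < sd_min
  bad_context <- ann$context %in% drop_contexts
  snp <- drop_snp & ann$snp_overlap
  cross <- drop_cross & ann$cross_reactive
  chry <- drop_chrY & ann$chrom == "Y"
  reasons <- cbind(low_sd = low_sd, context = bad_context, snp_overlap = snp,
                   cross_reactive = cross, chrY = chry)
  drop <- rowSums(reasons) > 0
  report <- tibble::tibble(
    probe_id = rep(rownames(beta), ncol(reasons)),
    reason = rep(colnames(reasons), each = nrow(beta)),
    flagged = as.vector(reasons)) |>
    dplyr::filter(.data$flagged) |>
    dplyr::select(-"flagged")
  list(beta = beta[!drop, , drop = FALSE], report = report,
       counts = c(colSums(reasons), removed = sum(drop),
                  retained = sum(!drop)))
}

#' k-nearest-neighbour imputation of missing beta values
#'
#' Each missing entry is replaced by the mean of the `k` nearest probes
#' (rows), nearness being root-mean-square Euclidean distance over the
#' samples both probes observe; only probes observed at the missing
#' entry's sample are eligible neighbours. Observed values are never
#' altered.
#'
#' @param beta probes x samples matrix with missing values.
#' @param k number of neighbours (default 10).
#' @param max_missing_frac error if any probe exceeds this missingness.
#' @return complete matrix.
#' @export
knn_impute <- function(beta, k = 10, max_missing_frac = 0.8) {
  stopifnot(k >= 1)
  miss_frac <- rowMeans(is.na(beta))
  if (any(miss_frac == 1))
    stop("probe(s) with no observed values cannot be imputed", call. = FALSE)
  if (any(miss_frac > max_missing_frac))
    stop("probe missingness exceeds max_missing_frac", call. = FALSE)
  if (!anyNA(beta)) return(beta)
  out <- beta
  need <- which(miss_frac > 0)
  obs_mat <- !is.na(beta)
  for (i in need) {
    xi <- beta[i, ]
    diff2 <- sweep(beta, 2, xi)^2
    shared <- obs_mat & matrix(rep(obs_mat[i, ], each = nrow(beta)),
                               nrow = nrow(beta))
    nshared <- rowSums(shared)
    d2 <- rowSums(diff2 * shared, na.rm = TRUE) / nshared
    d <- sqrt(d2)
    d[i] <- Inf
    d[nshared == 0] <- Inf
    for (j in which(is.na(beta[i, ]))) {
      cand <- which(obs_mat[, j] & is.finite(d))
      if (!length(cand))
        stop("no eligible neighbour for probe ", rownames(beta)[i], call. = FALSE)
      nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      out[i, j] <- mean(beta[nb, j])
    }
  }
  out
}

#' Per-sample global methylation level
#'
#' Arithmetic mean beta over all retained probes, the fraction of
#' methylated cytosine relative to total interrogated cytosine.
#'
#' @param beta complete probes x samples matrix.
#' @return tibble with `sample_id` and `global_methylation`.
#' @export
global_methylation <- function(beta) {
  if (nrow(beta) == 0) stop("empty probe set", call. = FALSE)
  if (anyNA(beta)) stop("matrix must be complete (impute first)", call. = FALSE)
  tibble::tibble(sample_id = colnames(beta),
                 global_methylation = unname(colMeans(beta)))
}

#' Paired Wilcoxon signed-rank test for a pre/post shift
#'
#' Two-sided signed-rank test of the paired differences, used for global
#' methylation, immune content and cell fractions. Zero differences are
#' handled by the Pratt convention; the exact null distribution is used
#' when there are no zeros or ties and n <= 25, otherwise a normal
#' approximation with continuity correction.
#'
#' @param metric_pre,metric_post equal-length paired numeric vectors.
#' @return two-sided p-value.
#' @export
paired_shift_test <- function(metric_pre, metric_post) {
  stopifnot(length(metric_pre) == length(metric_post))
  d <- metric_post - metric_pre
  if (all(d == 0)) {
    warning("all paired differences are zero; test degenerate", call. = FALSE)
    return(1)
  }
  nz <- d != 0
  # Pratt: |d| ranked including zeros; zero differences keep their ranks out
  # of the statistic and are not sign-flipped
  r <- rank(abs(d))
  W <- sum(r[d > 0]) - sum(r[d < 0])
  if (length(d) <= 25) {
    # exact sign-flip null of W by convolution over the signed (mid)ranks;
    # doubling makes midranks integral
    s <- as.integer(round(2 * r[nz]))
    M <- sum(s)
    probs <- numeric(2 * M + 1)       # support -M..M, index v + M + 1
    probs[M + 1] <- 1
    for (si in s) {
      up <- c(numeric(si), probs[seq_len(2 * M + 1 - si)])
      dn <- c(probs[-seq_len(si)], numeric(si))
      probs <- (up + dn) / 2
    }
    v <- abs(seq(-M, M))
    return(sum(probs[v >= abs(round(2 * W))]))
  }
  # normal approximation with continuity correction; the signs of non-zero
  # differences are iid +/-1 under H0, so Var(W) is the sum of their
  # squared (mid)ranks
  var_w <- sum(r[nz]^2)
  z <- (W - sign(W) * 0.5) / sqrt(var_w)
  2 * stats::pnorm(-abs(z))
}
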