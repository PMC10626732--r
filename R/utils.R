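# internal helpers shared across stages

clip01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

#' @importFrom stats rgamma
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# signed normal quantile of a two-sided p; stable for very small p via log scale
p_to_z <- function(p, sign_effect) {
  z <- stats::qnorm(log(p) - log(2), lower.tail = FALSE, log.p = TRUE)
  sign(sign_effect) * z
}

assert_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("`beta` must be a numeric matrix (probes x samples)", call. = FALSE)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("`beta` must have probe rownames and sample colnames", call. = FALSE)
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1]", call. = FALSE)
  invisible(beta)
}

# two-sample Kolmogorov-Smirnov statistic (no p-value machinery needed)
ks_stat <- function(x, y) {
  x <- sort(x); y <- sort(y)
  n <- length(x); m <- length(y)
  z <- c(x, y)
  ord <- order(z)
  d <- cumsum(ifelse(ord <= n, 1 / n, -1 / m))
  max(abs(d))
}
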