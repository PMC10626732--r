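# Brute-force reference implementations, independent of the package code,
# used to pin down the QC and enrichment primitives on small fixtures.

# independent oracle: literal restatement of the removal rule with explicit
# per-step recomputation over the surviving submatrix
greedycut_oracle <- function(detp, alpha = 0.01) {
  rows <- rownames(detp); cols <- colnames(detp)
  seqn <- character(0)
  repeat {
    m <- detp[rows, cols, drop = FALSE] > alpha
    if (!any(m) || length(rows) <= 1 || length(cols) <= 1) break
    rfrac <- apply(m, 1, mean); cfrac <- apply(m, 2, mean)
    if (max(rfrac) >= max(cfrac)) {
      worst <- names(rfrac)[which.max(rfrac)]
      rows <- setdiff(rows, worst)
    } else {
      worst <- names(cfrac)[which.max(cfrac)]
      cols <- setdiff(cols, worst)
    }
    seqn <- c(seqn, worst)
  }
  list(probes = rows, samples = cols, sequence = seqn)
}

knn_oracle <- function(beta, k) {
  out <- beta
  for (i in seq_len(nrow(beta))) for (j in seq_len(ncol(beta))) {
    if (!is.na(beta[i, j])) next
    d <- rep(Inf, nrow(beta))
    for (r in seq_len(nrow(beta))) {
      if (r == i || is.na(beta[r, j])) next
      sh <- which(!is.na(beta[i, ]) & !is.na(beta[r, ]))
      if (!length(sh)) next
      d[r] <- sqrt(mean((beta[i, sh] - beta[r, sh])^2))
    }
    nb <- order(d)[seq_len(k)]
    out[i, j] <- mean(beta[nb, j])
  }
  out
}

# literal position-by-position running-sum oracle
es_oracle <- function(stats, hit, exponent = 1) {
  N <- length(stats)
  nr <- sum(abs(stats[hit])^exponent)
  run <- numeric(N); cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) abs(stats[i])^exponent / nr else -1 / (N - sum(hit))
    run[i] <- cur
  }
  run[which.max(abs(run))]
}
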