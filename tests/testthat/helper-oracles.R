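# Naive reference implementations used as independent oracles. These stay
# deliberately loop-based and close to the formulas; the package's vectorized
# code is checked against them, never the other way around.

oracle_size_factors <- function(m) {
  sf <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    ratios <- numeric(nrow(m))
    for (g in seq_len(nrow(m))) {
      gm <- prod(m[g, ])^(1 / ncol(m))
      ratios[g] <- m[g, j] / gm
    }
    sf[j] <- median(ratios)
  }
  sf
}

# full running-sum enumeration of the weighted KS statistic
oracle_ks <- function(scores, members, p = 1) {
  ord <- order(-scores)
  hit <- members[ord]
  k <- sum(hit); G <- length(scores)
  w <- abs(scores[ord])^p
  W <- sum(w[hit])
  step <- ifelse(hit, if (W > 0) w / W else 1 / k, 0)
  step[!hit] <- -1 / (G - k)
  run <- cumsum(step)
  max_pos <- max(run, 0); min_neg <- min(run, 0)
  d <- max_pos + min_neg
  if (d > 1e-12) max_pos else if (d < -1e-12) min_neg else 0
}

oracle_gene_pvalues <- function(score_mat) {
  C <- ncol(score_mat)
  P <- matrix(0, nrow(score_mat), C)
  for (g in seq_len(nrow(score_mat))) {
    for (cc in seq_len(C)) {
      cnt <- 0L
      for (pp in seq_len(C))
        if (abs(score_mat[g, pp]) >= abs(score_mat[g, cc])) cnt <- cnt + 1L
      P[g, cc] <- cnt / C
    }
  }
  P
}

oracle_empirical_p <- function(obs, null, tail) {
  cnt <- 0L
  for (v in null)
    if ((tail == "greater" && v >= obs) || (tail == "smaller" && v <= obs))
      cnt <- cnt + 1L
  cnt / length(null)
}

oracle_fdr <- function(nas_obs, nas_null, tail) {
  m <- length(nas_obs); N <- ncol(nas_null)
  ge <- function(a, b) if (tail == "greater") a >= b else a <= b
  out <- numeric(m)
  for (i in seq_len(m)) {
    num <- 0
    for (pp in seq_len(N)) {
      cnt <- 0L
      for (j in seq_len(m)) if (ge(nas_null[j, pp], nas_obs[i])) cnt <- cnt + 1L
      num <- num + cnt / m
    }
    num <- num / N
    den <- 0L
    for (j in seq_len(m)) if (ge(nas_obs[j], nas_obs[i])) den <- den + 1L
    out[i] <- min(num / (den / m), 1)
  }
  out
}

oracle_fwer <- function(nas_obs, nas_null, tail) {
  m <- length(nas_obs); N <- ncol(nas_null)
  out <- numeric(m)
  for (i in seq_len(m)) {
    cnt <- 0L
    for (pp in seq_len(N)) {
      ext <- if (tail == "greater") max(nas_null[, pp]) else min(nas_null[, pp])
      hit <- if (tail == "greater") ext >= nas_obs[i] else ext <= nas_obs[i]
      if (hit) cnt <- cnt + 1L
    }
    out[i] <- cnt / N
  }
  out
}

# per-set, per-column naive AS references (same formulas, no vectorization)
oracle_as <- function(stat, scores, pvals, members, alpha = 0.05,
                      tau = 0.05, ks_p = 1, eps = 1e-16) {
  s <- scores[members]; p <- pvals[members]
  switch(stat,
    weighted_ks = oracle_ks(scores, members, ks_p),
    l2norm = sqrt(sum(s^2)),
    mean = mean(abs(s)),
    sig_ratio = sum(p <= alpha) / length(p),
    weighted_sig_ratio = sum(abs(s)[p <= alpha]) / length(s),
    geometric_mean = prod(pmax(p, eps))^(1 / length(p)),
    truncated_product = if (any(p <= tau)) prod(pmax(p[p <= tau], eps)) else 1,
    fisher = -2 * sum(log(pmax(p, eps))),
    min_p = min(p),
    rank_sum = {
      # naive midrank: 1 + #{strictly more significant} + (ties - 1) / 2
      n <- length(pvals); rk <- numeric(n)
      for (g in seq_len(n)) {
        more_sig <- sum(pvals < pvals[g] |
                          (pvals == pvals[g] & abs(scores) > abs(scores[g])))
        ties <- sum(pvals == pvals[g] & abs(scores) == abs(scores[g]))
        rk[g] <- more_sig + (ties + 1) / 2
      }
      sum(rk[members])
    })
}

# small deterministic fixture: counts with an inflated first gene set
tiny_dataset <- function(seed = 11L, n_genes = 60L, n_per_class = 8L,
                         n_sets = 6L, fc = 4) {
  set.seed(seed)
  mu <- 2^runif(n_genes, 4, 8)
  counts <- cbind(
    matrix(rnbinom(n_genes * n_per_class, mu = mu, size = 8), n_genes),
    matrix(rnbinom(n_genes * n_per_class,
                   mu = mu * c(rep(fc, 5), rep(1, n_genes - 5)), size = 8),
           n_genes))
  dimnames(counts) <- list(sprintf("g%02d", seq_len(n_genes)),
                           sprintf("s%02d", seq_len(2 * n_per_class)))
  labels <- factor(rep(c("A", "B"), each = n_per_class),
                   levels = c("A", "B"))
  sets <- lapply(seq_len(n_sets), function(i) {
    if (i == 1) rownames(counts)[1:8]
    else rownames(counts)[sample(6:n_genes, 10)]
  })
  names(sets) <- sprintf("ts%d", seq_len(n_sets))
  list(counts = counts, labels = labels, sets = sets)
}
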