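#' Build a permutation plan
#'
#' Sample mode draws N uniform shuffles of the phenotype label vector
#' (class sizes are preserved automatically since the whole vector is
#' permuted); gene mode draws N shuffles of the gene identities, applied to
#' the observed per-gene scores/p-values while labels stay fixed. The plan is
#' deterministic given the seed.
#'
#' @param labels Two-level factor of sample labels.
#' @param n_perm Number of permutations N (>= 1).
#' @param mode \code{"sample"} (default) or \code{"gene"}.
#' @param seed Integer seed.
#' @param n_genes Number of genes; required for gene mode.
#' @return List of class \code{"gsa_perm"}: \code{mode}, \code{n_perm},
#'   \code{seed}, and \code{idx}, an index matrix with one permutation per
#'   column (samples x N or genes x N).
#' @export
make_permutations <- function(labels, n_perm, mode = c("sample", "gene"),
                              seed = 1L, n_genes = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 1L) stop("n_perm must be at least 1")
  n <- if (mode == "sample") length(labels) else {
    if (is.null(n_genes)) stop("gene mode needs n_genes")
    n_genes
  }
  idx <- with_seed(seed, function()
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  structure(list(mode = mode, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), idx = idx), class = "gsa_perm")
}

#' Normalized association score
#'
#' AS divided by the mean of its permutation null, correcting for set-size
#' and correlation heterogeneity. For a signed statistic the observed AS is
#' divided by the mean of the same-signed null values (sign preserved); for
#' the non-negative statistics the plain null mean is used. If the required
#' null group is empty or has mean 0, NAS is reported as 0 with a warning.
#'
#' @param as_observed Observed AS (scalar).
#' @param as_null Numeric vector of N permutation AS values.
#' @param signed Is the statistic signed (Weighted_KS)?
#' @return The NAS.
#' @export
nas <- function(as_observed, as_null, signed = FALSE) {
  if (!length(as_null)) stop("empty permutation null")
  if (!signed) {
    mu <- mean(as_null)
    if (mu == 0) { warning("null mean is 0; NAS undefined, reporting 0"); return(0) }
    return(as_observed / mu)
  }
  grp <- if (as_observed >= 0) as_null[as_null >= 0] else as_null[as_null < 0]
  mu <- mean(abs(grp))
  if (!length(grp) || mu == 0) {
    warning("same-signed null group empty or zero-mean; NAS reported as 0")
    return(0)
  }
  sign_term <- if (as_observed >= 0) 1 else -1
  sign_term * abs(as_observed) / mu
}

#' Empirical permutation p-value for one set
#'
#' Plain-fraction tail probability with ties counted in the tail:
#' \code{#\{AS_pi >= AS_0\} / N} for the greater tail (score-family and
#' Fisher statistics), \code{#\{AS_pi <= AS_0\} / N} for the smaller tail
#' (p-value combination and rank statistics).
#'
#' @param as_observed Observed AS (scalar).
#' @param as_null Numeric vector of N permutation AS values.
#' @param tail \code{"greater"} or \code{"smaller"}.
#' @return p-value in [0, 1].
#' @export
empirical_p <- function(as_observed, as_null, tail = c("greater", "smaller")) {
  tail <- match.arg(tail)
  if (!length(as_null)) stop("empty permutation null")
  if (tail == "greater") mean(as_null >= as_observed)
  else mean(as_null <= as_observed)
}

#' Permutation FDR from normalized association scores
#'
#' For set i with the greater tail:
#' \deqn{FDR(S_i) = \frac{(1/N)\sum_\pi (1/m)\sum_j I(NAS(S_j,\pi) \ge NAS(S_i))}
#'                      {(1/m)\sum_j I(NAS(S_j) \ge NAS(S_i))}}
#' clipped to [0, 1]; the smaller tail replaces \eqn{\ge} by \eqn{\le}. The
#' denominator is never 0 because each set counts itself. No isotonic
#' adjustment beyond clipping is applied.
#'
#' @param nas_observed Numeric vector of observed NAS, one per set.
#' @param nas_null Matrix of null NAS, sets x N.
#' @param tail \code{"greater"} or \code{"smaller"}.
#' @return Numeric vector of FDR values in [0, 1].
#' @export
perm_fdr <- function(nas_observed, nas_null,
                     tail = c("greater", "smaller")) {
  tail <- match.arg(tail)
  pool <- sort.int(as.vector(nas_null), method = "quick")
  obs_sorted <- sort.int(nas_observed, method = "quick")
  if (tail == "greater") {
    num <- (length(pool) -
              findInterval(nas_observed, pool, left.open = TRUE)) /
      length(pool)
    den <- (length(obs_sorted) -
              findInterval(nas_observed, obs_sorted, left.open = TRUE)) /
      length(obs_sorted)
  } else {
    num <- findInterval(nas_observed, pool) / length(pool)
    den <- findInterval(nas_observed, obs_sorted) / length(obs_sorted)
  }
  pmin(num / den, 1)
}

#' Permutation FWER from normalized association scores
#'
#' Fraction of permutations whose most extreme per-permutation NAS reaches
#' the observed NAS of the set: the per-permutation maximum for the greater
#' tail, the minimum for the smaller tail.
#'
#' @inheritParams perm_fdr
#' @return Numeric vector of FWER values in [0, 1].
#' @export
perm_fwer <- function(nas_observed, nas_null,
                      tail = c("greater", "smaller")) {
  tail <- match.arg(tail)
  if (tail == "greater") {
    ext <- apply(nas_null, 2L, max)
    vapply(nas_observed, function(t0) mean(ext >= t0), 0)
  } else {
    ext <- apply(nas_null, 2L, min)
    vapply(nas_observed, function(t0) mean(ext <= t0), 0)
  }
}

# NAS / p / FDR / FWER for an AS matrix (sets x (1 + N)), dispatching on the
# tail and, for the signed Weighted_KS, working within same-sign groups
# (normalization by the same-signed null mean; p, FDR, FWER computed against
# the same-signed parts of the null).
set_significance <- function(as_mat, tail = c("greater", "smaller"),
                             signed = FALSE) {
  tail <- match.arg(tail)
  obs <- as_mat[, 1L]
  null <- as_mat[, -1L, drop = FALSE]
  N <- ncol(null)
  m <- nrow(as_mat)
  if (!signed) {
    mu <- rowMeans(null)
    bad <- mu == 0
    if (any(bad)) warning(sum(bad), " set(s) with zero null mean; NAS set to 0")
    mu[bad] <- Inf
    nas_obs <- obs / mu
    nas_null <- null / mu
    p <- if (tail == "greater") rowMeans(null >= obs) else
      rowMeans(null <= obs)
    fdr <- perm_fdr(nas_obs, nas_null, tail)
    fwer <- perm_fwer(nas_obs, nas_null, tail)
  } else {
    # same-sign normalization per set; zeros belong to the positive group
    mu_pos <- mu_neg <- numeric(m)
    for (i in seq_len(m)) {
      v <- null[i, ]
      mu_pos[i] <- mean(v[v >= 0])
      mu_neg[i] <- mean(abs(v[v < 0]))
    }
    norm1 <- function(x, mp, mn) {
      if (x >= 0) { if (is.finite(mp) && mp > 0) x / mp else 0 }
      else { if (is.finite(mn) && mn > 0) x / mn else 0 }
    }
    nas_obs <- vapply(seq_len(m), function(i)
      norm1(obs[i], mu_pos[i], mu_neg[i]), 0)
    nas_null <- null
    for (i in seq_len(m)) {
      v <- null[i, ]
      pos <- v >= 0
      nas_null[i, pos] <- if (is.finite(mu_pos[i]) && mu_pos[i] > 0)
        v[pos] / mu_pos[i] else 0
      nas_null[i, !pos] <- if (is.finite(mu_neg[i]) && mu_neg[i] > 0)
        v[!pos] / mu_neg[i] else 0
    }
    p <- vapply(seq_len(m), function(i) {
      v <- null[i, ]
      if (obs[i] >= 0) {
        g <- v[v >= 0]
        if (!length(g)) 1 else mean(g >= obs[i])
      } else {
        g <- v[v < 0]
        if (!length(g)) 1 else mean(g <= obs[i])
      }
    }, 0)
    pool <- as.vector(nas_null)
    pool_pos <- pool[pool >= 0]; pool_neg <- pool[pool < 0]
    obs_pos <- nas_obs[nas_obs >= 0]; obs_neg <- nas_obs[nas_obs < 0]
    fdr <- vapply(seq_len(m), function(i) {
      t0 <- nas_obs[i]
      if (t0 >= 0) {
        num <- if (length(pool_pos)) mean(pool_pos >= t0) else 0
        den <- if (length(obs_pos)) mean(obs_pos >= t0) else 1
      } else {
        num <- if (length(pool_neg)) mean(pool_neg <= t0) else 0
        den <- if (length(obs_neg)) mean(obs_neg <= t0) else 1
      }
      min(num / den, 1)
    }, 0)
    col_max <- apply(nas_null, 2L, max)
    col_min <- apply(nas_null, 2L, min)
    fwer <- vapply(seq_len(m), function(i) {
      if (nas_obs[i] >= 0) mean(col_max >= nas_obs[i])
      else mean(col_min <= nas_obs[i])
    }, 0)
  }
  data.frame(AS = obs, NAS = nas_obs, PVALUE = p, FDR = fdr, FWER = fwer,
             row.names = rownames(as_mat))
}

#' Run the full gene set association analysis
#'
#' Normalizes the counts (+1 pseudocount, median-of-ratios), filters gene
#' sets to the intersected size window, computes per-gene differential
#' expression scores for the observed labels and N permutations, aggregates
#' them into per-set association scores, and derives NAS, empirical
#' p-values, FDR, and FWER from the permutation null. Results are identical
#' for identical seeds.
#'
#' In \code{perm_type = "sample"} mode the phenotype labels are shuffled and
#' all gene statistics recomputed per permutation (preserving gene-gene
#' correlation in the null); per-gene p-values are two-sided empirical tail
#' probabilities against each gene's own permutation null. In \code{"gene"}
#' mode the observed gene scores are shuffled across gene identities, and
#' per-gene p-values are cross-gene tail probabilities
#' \code{#\{h: |s_h| >= |s_g|\} / G} (the gene-permutation null itself).
#'
#' @param counts Raw count matrix (genes x samples, dimnames required).
#' @param labels Two-level factor over the sample columns (positional
#'   alignment, as in the CLS format); first level = reference class.
#' @param sets Named list of gene identifier vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param gene_stat One of \code{"signal2noise"} (default),
#'   \code{"log2ratio"}, \code{"signal2noise_log2ratio"}.
#' @param set_stat One of the ten ids in \code{\link{set_stat_info}}
#'   (default \code{"l2norm"}).
#' @param n_perm Number of permutations (default 2000).
#' @param perm_type \code{"sample"} (default) or \code{"gene"}.
#' @param seed Integer seed for the permutation stream.
#' @param min_size,max_size Inclusive bounds on intersected set size
#'   (defaults 15 and 100).
#' @param alpha Gene-significance threshold for the ratio statistics.
#' @param tau Truncation threshold for the truncated product.
#' @param ks_exponent Weight exponent for Weighted_KS.
#' @return Object of class \code{"gsa_result"}: a list with \code{table}
#'   (data frame NAME, SIZE, AS, NAS, PVALUE, FDR, FWER, sorted by FDR then
#'   NAS extremity) and the run settings.
#' @examples
#' sim <- simulate_dataset(scenario_config("S6", seed = 1,
#'   n_genes = 120, n_samples_per_class = 20, n_sets = 10,
#'   set_size_range = c(5, 20)))
#' res <- run_gsa(sim$counts, sim$labels, sim$sets, n_perm = 50,
#'                min_size = 3, max_size = 50, seed = 1)
#' head(res$table, 3)
#' @export
run_gsa <- function(counts, labels, sets,
                    gene_stat = c("signal2noise", "log2ratio",
                                  "signal2noise_log2ratio"),
                    set_stat = "l2norm", n_perm = 2000L,
                    perm_type = c("sample", "gene"), seed = 1L,
                    min_size = 15L, max_size = 100L, alpha = 0.05,
                    tau = 0.05, ks_exponent = 1) {
  gene_stat <- match.arg(gene_stat)
  set_stat <- match.arg(set_stat, SET_STATS)
  perm_type <- match.arg(perm_type)
  validate_counts(counts)
  validate_labels(labels)
  if (length(labels) != ncol(counts))
    stop("labels length (", length(labels), ") != number of samples (",
         ncol(counts), ")")
  norm <- normalize_counts(counts)
  fsets <- filter_gene_sets(sets, rownames(counts), min_size, max_size)
  if (!length(fsets)) stop("no gene sets left after size filtering")
  sets_idx <- lapply(fsets, function(g) match(g, rownames(counts)))
  info <- set_stat_info()
  info <- info[info$id == set_stat, ]
  plan <- make_permutations(labels, n_perm, perm_type, seed,
                            n_genes = nrow(counts))
  need_p <- info$family %in% c("pvalue", "rank") ||
    set_stat %in% c("sig_ratio", "weighted_sig_ratio")
  # permutations are drawn in ID-sorted (canonical) space so that jointly
  # reordering input columns and labels (or gene rows) cannot change results
  if (perm_type == "sample") {
    canon <- order(colnames(counts))
    inv <- integer(length(canon)); inv[canon] <- seq_along(canon)
    lc1 <- (labels == levels(labels)[1L])[canon]
    perm_memb <- matrix(lc1[plan$idx], nrow = length(labels))
    memb <- cbind(labels == levels(labels)[1L],
                  perm_memb[inv, , drop = FALSE])
    scores <- gene_score_matrix(norm$values, memb, gene_stat)
    pvals <- if (need_p) gene_pvalues(scores) else NULL
  } else {
    canon <- order(rownames(counts))
    inv <- integer(length(canon)); inv[canon] <- seq_along(canon)
    obs_scores <- gene_scores_observed(norm$values, labels, gene_stat)
    sc <- obs_scores[canon]
    scores <- cbind(obs_scores,
                    matrix(sc[plan$idx],
                           nrow = length(obs_scores))[inv, , drop = FALSE])
    if (need_p) {
      a <- abs(obs_scores)
      obs_p <- vapply(a, function(v) mean(a >= v), 0)
      pc <- obs_p[canon]
      pvals <- cbind(obs_p,
                     matrix(pc[plan$idx],
                            nrow = length(obs_p))[inv, , drop = FALSE])
    } else pvals <- NULL
  }
  as_mat <- compute_as_matrix(set_stat, sets_idx, scores = scores,
                              pvalues = pvals, alpha = alpha, tau = tau,
                              ks_exponent = ks_exponent,
                              eps = 1 / (10 * n_perm))
  sig <- set_significance(as_mat, tail = info$tail, signed = info$signed)
  table <- data.frame(NAME = rownames(as_mat), SIZE = lengths(sets_idx),
                      sig, row.names = NULL, stringsAsFactors = FALSE)
  table <- sort_results(table)
  rownames(table) <- NULL
  structure(list(table = table, gene_stat = gene_stat, set_stat = set_stat,
                 n_perm = as.integer(n_perm), perm_type = perm_type,
                 seed = as.integer(seed), min_size = min_size,
                 max_size = max_size, alpha = alpha, tau = tau,
                 ks_exponent = ks_exponent,
                 n_genes = nrow(counts), n_sets = length(fsets),
                 size_factors = norm$size_factors),
            class = "gsa_result")
}

#' @export
print.gsa_result <- function(x, ...) {
  cat("Gene set association analysis (", x$gene_stat, ":", x$set_stat,
      ", ", x$perm_type, " permutation, N = ", x$n_perm, ")\n",
      x$n_sets, " gene sets over ", x$n_genes, " genes\n\n", sep = "")
  print(utils::head(x$table, 10L), digits = 4)
  if (nrow(x$table) > 10L) cat("... ", nrow(x$table) - 10L, " more sets\n")
  invisible(x)
}
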