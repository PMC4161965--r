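#' Set-level statistic registry
#'
#' Ten gene set association statistics in three input families. The
#' \code{family} determines the input (gene scores, gene p-values, or global
#' significance ranks); the \code{tail} fixes the direction in which the
#' statistic signals association: \code{"greater"} means larger AS is more
#' significant, \code{"smaller"} the opposite. Weighted_KS is signed and its
#' significance machinery works within same-sign groups.
#'
#' @format Data frame with columns \code{id}, \code{family}, \code{tail},
#'   \code{signed}.
#' @export
set_stat_info <- function() {
  data.frame(
    id = c("weighted_ks", "l2norm", "mean", "weighted_sig_ratio", "sig_ratio",
           "geometric_mean", "truncated_product", "fisher", "min_p",
           "rank_sum"),
    family = c("score", "score", "score", "score", "score",
               "pvalue", "pvalue", "pvalue", "pvalue", "rank"),
    tail = c("greater", "greater", "greater", "greater", "greater",
             "smaller", "smaller", "greater", "smaller", "smaller"),
    signed = c(TRUE, rep(FALSE, 9L)),
    stringsAsFactors = FALSE
  )
}

SET_STATS <- c("weighted_ks", "l2norm", "mean", "weighted_sig_ratio",
               "sig_ratio", "geometric_mean", "truncated_product", "fisher",
               "min_p", "rank_sum")

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Genes are ranked by decreasing score (ties keep original order); a running
#' sum increases by \code{|score|^p / sum_set |score|^p} at member genes and
#' decreases by \code{1 / (G - k)} at non-members. The association score is
#' the running-sum value of maximum absolute deviation from zero (signed);
#' if the positive and negative extremes tie exactly in magnitude the score
#' is 0, a deterministic convention shared with other implementations of the
#' statistic. If all member weights are zero, equal weights are used.
#'
#' @param gene_scores Signed per-gene scores (all genes).
#' @param member_flags Logical vector marking set members.
#' @param weight_exponent Weight exponent p (default 1, the weighted
#'   setting; 0 gives the classic KS statistic).
#' @return Signed enrichment score.
#' @export
weighted_ks <- function(gene_scores, member_flags, weight_exponent = 1) {
  G <- length(gene_scores)
  k <- sum(member_flags)
  if (k < 1L) stop("empty gene set")
  if (k >= G) stop("gene set covers all genes; miss penalty undefined")
  ord <- order(-gene_scores)
  inv <- integer(G); inv[ord] <- seq_len(G)
  pos <- sort.int(inv[which(member_flags)])
  w <- abs(gene_scores[ord][pos])^weight_exponent
  W <- sum(w)
  hits <- if (W > 0) cumsum(w) / W else seq_len(k) / k
  gaps <- (pos - seq_len(k)) / (G - k)
  ks_pick(max(hits - gaps, 0), min(c(0, hits[-k]) - gaps, 0))
}

# deterministic extreme selection: positive extreme wins iff strictly larger
# in magnitude; magnitude ties give 0. Exact rational ties are structurally
# common (hit weights sum to 1, miss penalties are rational), so the tie is
# detected within a small band to keep it independent of summation order.
ks_pick <- function(max_pos, min_neg, tol = 1e-12) {
  d <- max_pos + min_neg
  if (d > tol) max_pos else if (d < -tol) min_neg else 0
}

#' L2 norm association score
#'
#' \code{sqrt(sum(score^2))} over member gene scores; sign-invariant, so up-
#' and down-regulated members contribute alike.
#'
#' @param set_scores Member gene scores.
#' @return Non-negative association score.
#' @export
l2norm <- function(set_scores) {
  if (!length(set_scores)) stop("empty gene set")
  sqrt(sum(set_scores^2))
}

#' Mean absolute-score association score
#'
#' Mean of \code{|score|} over member genes. Absolute values keep
#' down-regulated causal sets visible under the one-sided (greater-tail)
#' significance convention of the score family.
#'
#' @param set_scores Member gene scores.
#' @return Non-negative association score.
#' @export
mean_abs <- function(set_scores) {
  if (!length(set_scores)) stop("empty gene set")
  mean(abs(set_scores))
}

#' Significant-gene ratio
#'
#' Fraction of member genes with p-value at or below \code{alpha}.
#'
#' @param set_pvalues Member gene p-values.
#' @param alpha Significance threshold (default 0.05).
#' @return Association score in [0, 1].
#' @export
sig_ratio <- function(set_pvalues, alpha = 0.05) {
  if (!length(set_pvalues)) stop("empty gene set")
  stopifnot(alpha > 0, alpha < 1)
  mean(set_pvalues <= alpha)
}

#' Score-weighted significant-gene ratio
#'
#' Sum of \code{|score|} over member genes with p-value at or below
#' \code{alpha}, divided by the set size: the significant proportion weighted
#' by effect magnitude.
#'
#' @param set_scores Member gene scores (aligned with \code{set_pvalues}).
#' @param set_pvalues Member gene p-values.
#' @param alpha Significance threshold (default 0.05).
#' @return Non-negative association score.
#' @export
weighted_sig_ratio <- function(set_scores, set_pvalues, alpha = 0.05) {
  if (!length(set_scores)) stop("empty gene set")
  stopifnot(length(set_scores) == length(set_pvalues), alpha > 0, alpha < 1)
  sum(abs(set_scores)[set_pvalues <= alpha]) / length(set_scores)
}

#' Geometric mean of member p-values
#'
#' \code{(prod p_i)^(1/k)}; p-values are clamped at \code{eps} before the
#' logarithm so empirical zeros stay finite.
#'
#' @param set_pvalues Member gene p-values.
#' @param eps Lower clamp (default 1e-16; the pipeline uses 1/(10 N)).
#' @return Association score in (0, 1]; smaller is more significant.
#' @export
geometric_mean_p <- function(set_pvalues, eps = 1e-16) {
  if (!length(set_pvalues)) stop("empty gene set")
  exp(mean(log(pmax(set_pvalues, eps))))
}

#' Truncated product of member p-values
#'
#' Product of the member p-values at or below the truncation point
#' \code{tau}; 1 (empty product) when none qualify.
#'
#' @param set_pvalues Member gene p-values.
#' @param tau Truncation threshold (default 0.05).
#' @param eps Lower clamp applied before multiplying.
#' @return Association score in (0, 1]; smaller is more significant.
#' @export
truncated_product <- function(set_pvalues, tau = 0.05, eps = 1e-16) {
  if (!length(set_pvalues)) stop("empty gene set")
  stopifnot(tau > 0, tau < 1)
  keep <- set_pvalues <= tau
  if (!any(keep)) return(1)
  exp(sum(log(pmax(set_pvalues[keep], eps))))
}

#' Fisher's combination of member p-values
#'
#' \code{-2 sum(log p_i)} with the same lower clamp as
#' \code{\link{geometric_mean_p}}; larger is more significant.
#'
#' @param set_pvalues Member gene p-values.
#' @param eps Lower clamp.
#' @return Non-negative association score.
#' @export
fisher_method <- function(set_pvalues, eps = 1e-16) {
  if (!length(set_pvalues)) stop("empty gene set")
  -2 * sum(log(pmax(set_pvalues, eps)))
}

#' Minimum member p-value
#'
#' @param set_pvalues Member gene p-values.
#' @return Association score in [0, 1]; smaller is more significant.
#' @export
min_p <- function(set_pvalues) {
  if (!length(set_pvalues)) stop("empty gene set")
  min(set_pvalues)
}

#' Rank-sum association score
#'
#' Sum of the member genes' global significance ranks (rank 1 = most
#' significant gene; ties averaged). Smaller is more significant.
#'
#' @param global_gene_ranks Significance ranks over all genes (see
#'   \code{gsaperm:::sig_ranks}).
#' @param member_flags Logical vector marking set members.
#' @return Positive association score.
#' @export
rank_sum <- function(global_gene_ranks, member_flags) {
  if (!any(member_flags)) stop("empty gene set")
  sum(global_gene_ranks[member_flags])
}

# AS matrix for one statistic over all sets and all columns (observed +
# permutations). scores / pvalues: genes x C matrices (either may be NULL if
# the statistic does not need it). sets_idx: list of integer index vectors
# into the gene dimension. Returns sets x C matrix.
compute_as_matrix <- function(set_stat, sets_idx, scores = NULL,
                              pvalues = NULL, alpha = 0.05, tau = 0.05,
                              ks_exponent = 1, eps = 1e-16) {
  set_stat <- match.arg(set_stat, SET_STATS)
  m <- length(sets_idx)
  if (!m) stop("no gene sets to score")
  G <- nrow(if (!is.null(scores)) scores else pvalues)
  C <- ncol(if (!is.null(scores)) scores else pvalues)
  bad <- vapply(sets_idx, function(ix) length(ix) < 1L || length(ix) >= G,
                TRUE)
  if (any(bad)) stop("gene sets must be non-empty and smaller than the data")
  # membership indicator for the matrix-product statistics
  memb <- matrix(0, m, G)
  for (i in seq_len(m)) memb[i, sets_idx[[i]]] <- 1
  sizes <- lengths(sets_idx)
  as_mat <- switch(set_stat,
    l2norm = sqrt(memb %*% (scores * scores)),
    mean = (memb %*% abs(scores)) / sizes,
    sig_ratio = (memb %*% (pvalues <= alpha)) / sizes,
    weighted_sig_ratio = (memb %*% (abs(scores) * (pvalues <= alpha))) / sizes,
    geometric_mean = exp((memb %*% log(pmax(pvalues, eps))) / sizes),
    truncated_product = exp(memb %*% (log(pmax(pvalues, eps)) *
                                        (pvalues <= tau))),
    fisher = -2 * (memb %*% log(pmax(pvalues, eps))),
    min_p = {
      out <- matrix(0, m, C)
      for (i in seq_len(m))
        out[i, ] <- do.call(pmin, asplit(
          pvalues[sets_idx[[i]], , drop = FALSE], 1L))
      out
    },
    rank_sum = {
      rk <- matrix(0, G, C)
      for (cc in seq_len(C))
        rk[, cc] <- sig_ranks(pvalues[, cc], scores[, cc])
      memb %*% rk
    },
    weighted_ks = {
      # rank each column once, then O(k) per set from member positions
      out <- matrix(0, m, C)
      for (cc in seq_len(C)) {
        s <- scores[, cc]
        ord <- order(-s)
        inv <- integer(G); inv[ord] <- seq_len(G)
        aw_ord <- abs(s[ord])^ks_exponent
        for (i in seq_len(m)) {
          pos <- sort.int(inv[sets_idx[[i]]])
          k <- length(pos)
          w <- aw_ord[pos]
          W <- sum(w)
          hits <- if (W > 0) cumsum(w) / W else seq_len(k) / k
          gaps <- (pos - seq_len(k)) / (G - k)
          out[i, cc] <- ks_pick(max(hits - gaps, 0),
                                min(c(0, hits[-k]) - gaps, 0))
        }
      }
      out
    }
  )
  as_mat <- as.matrix(as_mat)
  rownames(as_mat) <- names(sets_idx)
  as_mat
}
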