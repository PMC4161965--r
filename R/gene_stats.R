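GENE_STATS <- c("signal2noise", "log2ratio", "signal2noise_log2ratio")

# Column-wise class-1 membership matrix for a label factor: samples x C
# logical matrix, column 1 = observed assignment, remaining columns permuted
# assignments. Used to vectorize gene statistics over permutations.
class1_membership <- function(labels, perm_idx = NULL) {
  obs <- labels == levels(labels)[1L]
  if (is.null(perm_idx)) return(matrix(obs, ncol = 1L))
  cbind(obs, matrix(obs[perm_idx], nrow = length(obs)))
}

# Vectorized gene scores: values (genes x samples), memb (samples x C
# logical). Returns genes x C matrix of scores, one column per label
# assignment. The Signal2Noise class sd is floored at
# max(sd, 0.2 * |class mean|, 1e-8), guarding near-constant genes.
gene_score_matrix <- function(values, memb, stat = GENE_STATS) {
  stat <- match.arg(stat)
  storage.mode(memb) <- "double"
  n1 <- sum(memb[, 1L])
  n2 <- nrow(memb) - n1
  if (n1 < 2L || n2 < 2L)
    stop("each phenotype class needs at least 2 samples")
  S1 <- values %*% memb
  tot <- rowSums(values)
  M1 <- S1 / n1
  M2 <- (tot - S1) / n2
  if (stat == "log2ratio") return(log2(M1 / M2))
  Q1 <- (values * values) %*% memb
  qtot <- rowSums(values * values)
  V1 <- (Q1 - n1 * M1 * M1) / (n1 - 1)
  V2 <- ((qtot - Q1) - n2 * M2 * M2) / (n2 - 1)
  sd1 <- pmax(sqrt(pmax(V1, 0)), 0.2 * abs(M1), 1e-8)
  sd2 <- pmax(sqrt(pmax(V2, 0)), 0.2 * abs(M2), 1e-8)
  s2n <- (M1 - M2) / (sd1 + sd2)
  if (stat == "signal2noise") return(s2n)
  lr <- log2(M1 / M2)
  sign(lr) * sqrt(abs(s2n) * abs(lr))
}

gene_scores_observed <- function(values, labels, stat) {
  validate_labels(labels)
  drop(gene_score_matrix(values, class1_membership(labels), stat))
}

#' Signal-to-noise gene statistic
#'
#' For each gene, the difference of class means divided by the sum of class
#' standard deviations, \code{(m1 - m2) / (s1 + s2)}, where each class sd is
#' floored at \code{max(sd, 0.2 |m|, 1e-8)}. Positive scores mean higher
#' expression in the first (reference) class.
#'
#' @param values Positive normalized expression matrix (genes x samples).
#' @param labels Two-level factor over the sample columns; the first level is
#'   the reference class.
#' @return Named numeric vector of per-gene scores.
#' @export
signal2noise <- function(values, labels)
  gene_scores_observed(values, labels, "signal2noise")

#' Log2 ratio of class means
#'
#' \code{log2(m1 / m2)} per gene; requires strictly positive values
#' (guaranteed after the +1 pseudocount).
#'
#' @inheritParams signal2noise
#' @return Named numeric vector of per-gene scores.
#' @export
log2ratio <- function(values, labels)
  gene_scores_observed(values, labels, "log2ratio")

#' Combined signal-to-noise / log2-ratio gene statistic
#'
#' Sign-preserving geometric mean of the two component magnitudes:
#' \code{sign(M) * sqrt(|S| * |M|)} with \code{S} the signal-to-noise score
#' and \code{M} the log2 ratio. Zero iff either component is zero, and
#' antisymmetric under class swap like both components.
#'
#' @inheritParams signal2noise
#' @return Named numeric vector of per-gene scores.
#' @export
signal2noise_log2ratio <- function(values, labels)
  gene_scores_observed(values, labels, "signal2noise_log2ratio")

#' Per-gene empirical permutation p-values
#'
#' Two-sided empirical p-values against each gene's own permutation null:
#' for column c of the score matrix (column 1 = observed, the rest
#' label-permutation scores), \code{p[g, c]} is the fraction of all 1 + N
#' columns whose \code{|score|} is at least \code{|score[g, c]|}, ties
#' counted in the tail. Every column -- observed or permuted -- is scored
#' against the same pooled collection (which contains the column itself, so
#' p is at least 1/(1 + N)). Treating the observed assignment as one more
#' member of the permutation ensemble keeps the columns exchangeable under
#' the null, which is what makes set statistics built from these p-values
#' calibrated; it is the standard unbiased convention for permutation
#' p-values.
#'
#' @param score_mat Numeric matrix, genes x (1 + N): observed scores in
#'   column 1, permutation scores in the remaining N columns.
#' @return Matrix of the same shape with values in (0, 1].
#' @export
gene_pvalues <- function(score_mat) {
  stopifnot(is.matrix(score_mat), ncol(score_mat) >= 2L)
  C <- ncol(score_mat)
  A <- abs(score_mat)
  P <- matrix(0, nrow(A), C, dimnames = dimnames(score_mat))
  for (g in seq_len(nrow(A))) {
    pool_sorted <- sort.int(A[g, ], method = "quick")
    P[g, ] <- C - findInterval(A[g, ], pool_sorted, left.open = TRUE)
  }
  P / C
}

# Significance ranks over all genes: rank 1 = smallest p-value, ties broken
# by larger |score|, residual exact ties get the average rank.
sig_ranks <- function(pvalues, scores) {
  a <- abs(scores)
  o <- order(pvalues, -a)
  p_o <- pvalues[o]; a_o <- a[o]
  n <- length(o)
  new_grp <- c(TRUE, p_o[-1L] != p_o[-n] | a_o[-1L] != a_o[-n])
  grp <- cumsum(new_grp)
  r <- stats::ave(seq_len(n), grp)
  out <- numeric(n)
  out[o] <- r
  out
}
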