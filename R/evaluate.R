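#' Recognition rate over simulation replicates
#'
#' Proportion of replicates in which the causal gene set is the top-ranked
#' set after the FDR-then-NAS sort of the result table.
#'
#' @param replicate_tables List of result tables (data frames from
#'   \code{run_gsa()$table} or \code{\link{read_results}}).
#' @param causal_name Name of the causal set; must be present in every table.
#' @return Proportion in [0, 1].
#' @export
recognition_rate <- function(replicate_tables, causal_name) {
  top <- vapply(replicate_tables, function(tab) {
    if (!causal_name %in% tab$NAME)
      stop("causal set '", causal_name, "' missing from a result table")
    sort_results(tab)$NAME[1L]
  }, "")
  mean(top == causal_name)
}

#' Power over simulation replicates
#'
#' Proportion of replicates in which the causal set's empirical p-value is
#' strictly below the threshold.
#'
#' @inheritParams recognition_rate
#' @param threshold Significance threshold (default 0.05, strict).
#' @return Proportion in [0, 1].
#' @export
gsa_power <- function(replicate_tables, causal_name, threshold = 0.05) {
  p <- vapply(replicate_tables, function(tab) {
    i <- match(causal_name, tab$NAME)
    if (is.na(i))
      stop("causal set '", causal_name, "' missing from a result table")
    tab$PVALUE[i]
  }, 0)
  mean(p < threshold)
}

#' Cross-replicate evaluation summary
#'
#' Recognition rate, power, and mean p-value / FDR / FWER of the causal set
#' over a list of replicate result tables.
#'
#' @inheritParams gsa_power
#' @return One-row data frame: recognition_rate, power, mean_p, mean_fdr,
#'   mean_fwer, n_replicates.
#' @export
evaluation_summary <- function(replicate_tables, causal_name,
                               threshold = 0.05) {
  rows <- lapply(replicate_tables, function(tab) {
    tab[match(causal_name, tab$NAME), c("PVALUE", "FDR", "FWER")]
  })
  rows <- do.call(rbind, rows)
  data.frame(recognition_rate = recognition_rate(replicate_tables,
                                                 causal_name),
             power = gsa_power(replicate_tables, causal_name, threshold),
             mean_p = mean(rows$PVALUE), mean_fdr = mean(rows$FDR),
             mean_fwer = mean(rows$FWER),
             n_replicates = length(replicate_tables))
}

#' Aggregate a pathway-by-method rank matrix
#'
#' Given per-method ranks (0 = not in the method's top K), computes NOC
#' (number of methods ranking the pathway) and Avg (mean of the non-zero
#' ranks), keeps pathways ranked by at least \code{min_methods} methods, and
#' sorts by Avg ascending (ties by larger NOC, then name).
#'
#' @param ranks Numeric matrix, pathways x methods, with pathway row names;
#'   0 marks absence from a method's top K.
#' @param min_methods Minimum number of methods (default 4).
#' @return Data frame: Index (G1, G2, ...), Pathway, NOC, one column per
#'   method, Avg.
#' @export
aggregate_rank_matrix <- function(ranks, min_methods = 4L) {
  stopifnot(is.matrix(ranks), !is.null(rownames(ranks)), min_methods >= 1L)
  noc <- rowSums(ranks > 0)
  avg <- ifelse(noc > 0, rowSums(ranks) / noc, NA_real_)
  keep <- noc >= min_methods
  out <- data.frame(Pathway = rownames(ranks)[keep], NOC = noc[keep],
                    ranks[keep, , drop = FALSE], Avg = avg[keep],
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[order(out$Avg, -out$NOC, out$Pathway), , drop = FALSE]
  out <- cbind(Index = sprintf("G%d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Top-K occurrence / average-rank aggregation across methods
#'
#' Extracts each method's top \code{top_k} pathways (after the FDR-then-NAS
#' sort), records each pathway's rank per method (0 outside the top K), and
#' aggregates with \code{\link{aggregate_rank_matrix}}: pathways ranked in
#' the top K by at least \code{min_methods} methods, ordered by their
#' average rank across the methods that listed them.
#'
#' @param tables_by_method Named list of result tables, one per method.
#' @param top_k Top-list depth (default 30).
#' @param min_methods Minimum number of methods (default 4).
#' @return Data frame as in \code{\link{aggregate_rank_matrix}}, with one
#'   rank column per method name.
#' @export
aggregate_ranks <- function(tables_by_method, top_k = 30L,
                            min_methods = 4L) {
  stopifnot(top_k >= 1L, length(tables_by_method) >= 1L)
  if (is.null(names(tables_by_method)))
    names(tables_by_method) <- sprintf("method_%d",
                                       seq_along(tables_by_method))
  tops <- lapply(tables_by_method, function(tab)
    utils::head(sort_results(tab)$NAME, top_k))
  pathways <- unique(unlist(tops))
  ranks <- vapply(tops, function(tk) {
    r <- match(pathways, tk)
    ifelse(is.na(r), 0L, r)
  }, integer(length(pathways)))
  ranks <- matrix(ranks, nrow = length(pathways),
                  dimnames = list(pathways, names(tables_by_method)))
  aggregate_rank_matrix(ranks, min_methods)
}

#' Read a pathway-by-method rank matrix from TSV
#'
#' Expects a Pathway column plus one numeric column per method (0 = absent);
#' extra non-rank columns named Index, NOC, or Avg are ignored so published
#' aggregation tables can be re-read directly.
#'
#' @param path TSV file path.
#' @return Numeric matrix with pathway row names.
#' @export
read_rank_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  stopifnot("Pathway" %in% names(tab))
  drop <- intersect(c("Index", "NOC", "Avg"), names(tab))
  m <- as.matrix(tab[, setdiff(names(tab), c("Pathway", drop)),
                     drop = FALSE])
  rownames(m) <- tab$Pathway
  storage.mode(m) <- "double"
  m
}
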