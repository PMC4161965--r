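#' Add a pseudocount of 1 to every entry
#'
#' Applied before normalization so that geometric means and log ratios are
#' defined for genes with zero counts in some samples.
#'
#' @param counts Count matrix.
#' @return Matrix with every entry incremented by 1.
#' @export
add_pseudocount <- function(counts) counts + 1

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants: the size factor of sample j is the median
#' over genes of counts[g, j] divided by the geometric mean of gene g across
#' samples. All entries must be strictly positive (apply
#' \code{\link{add_pseudocount}} first).
#'
#' @param counts Strictly positive matrix (genes x samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- matrix(c(2, 6, 4, 12), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' deseq_size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
deseq_size_factors <- function(counts) {
  if (any(counts <= 0))
    stop("size factors need strictly positive counts; add a pseudocount first")
  log_gm <- rowMeans(log(counts))
  sf <- apply(counts, 2L, function(col) exp(stats::median(log(col) - log_gm)))
  stats::setNames(sf, colnames(counts))
}

#' Normalize a count matrix
#'
#' Adds the +1 pseudocount, computes median-of-ratios size factors on the
#' pseudocounted matrix, and divides each sample column by its factor.
#'
#' @param counts Non-negative count matrix.
#' @return List with class \code{"gsa_norm"}: \code{values} (positive
#'   normalized matrix) and \code{size_factors}.
#' @export
normalize_counts <- function(counts) {
  pc <- add_pseudocount(counts)
  sf <- deseq_size_factors(pc)
  structure(list(values = sweep(pc, 2L, sf, "/"), size_factors = sf),
            class = "gsa_norm")
}

#' Filter gene sets by intersected size
#'
#' Intersects each set with the genes present in the data and keeps sets
#' whose intersected size lies in \code{[min_size, max_size]} (both
#' inclusive). Retained sets store the intersected gene lists, so downstream
#' SIZE columns reflect genes actually measured.
#'
#' @param sets Named list of gene identifier vectors.
#' @param data_genes Character vector of gene identifiers present in the data.
#' @param min_size,max_size Inclusive size bounds (defaults 15 and 100, the
#'   conventional bounds that exclude overly narrow or broad pathways).
#' @return Filtered collection (named list, descriptions preserved); warns if
#'   empty.
#' @export
filter_gene_sets <- function(sets, data_genes, min_size = 15L,
                             max_size = 100L) {
  stopifnot(min_size >= 1L, max_size >= min_size)
  trimmed <- lapply(sets, function(g) g[g %in% data_genes])
  keep <- lengths(trimmed) >= min_size & lengths(trimmed) <= max_size
  out <- trimmed[keep]
  desc <- attr(sets, "description")
  if (!is.null(desc)) attr(out, "description") <- desc[names(out)]
  if (!length(out))
    warning("no gene sets within size bounds [", min_size, ", ", max_size, "]")
  out
}
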