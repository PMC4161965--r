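#' Read a gene-by-sample count matrix
#'
#' Reads a tab-delimited count table (gene identifiers in the first column,
#' one sample per remaining column) or a GCT 1.2 file (two header lines and a
#' Description column, which is ignored). Row and column order are preserved
#' from the file.
#'
#' @param path Path to the file.
#' @param dialect \code{"tsv"}, \code{"gct"}, or \code{"auto"} (default:
#'   detect GCT by its \code{#1.2} first line).
#' @return A numeric matrix of non-negative counts with gene identifiers as
#'   row names and sample identifiers as column names.
#' @examples
#' f <- tempfile()
#' writeLines(c("NAME\ts1\ts2", "G1\t0\t1", "G2\t3\t4"), f)
#' read_counts(f)
#' @export
read_counts <- function(path, dialect = c("auto", "tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("count file not found: ", path)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (identical(trimws(first), "#1.2")) "gct" else "tsv"
  }
  skip <- if (dialect == "gct") 2L else 0L
  tab <- utils::read.delim(path, skip = skip, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("count file has no sample columns: ", path)
  gene_ids <- as.character(tab[[1L]])
  drop <- 1L
  if (dialect == "gct") {
    if (ncol(tab) < 3L) stop("GCT file has no sample columns: ", path)
    drop <- c(1L, 2L)  # NAME, Description
  }
  m <- as.matrix(tab[, -drop, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count entries in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  validate_counts(m)
  m
}

#' Validate a count matrix
#'
#' Checks identifier uniqueness, finiteness, and non-negativity. Called by
#' the readers and by \code{\link{run_gsa}}; exported so synthetic matrices
#' can be checked directly.
#'
#' @param counts Numeric matrix with gene row names and sample column names.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene row names and sample column names")
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup))
    stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "))
  if (any(!is.finite(counts))) stop("counts contain non-finite values")
  if (any(counts < 0)) stop("counts contain negative values")
  invisible(counts)
}

#' Write a count matrix
#'
#' @param counts Count matrix (genes x samples, dimnames required).
#' @param path Output path.
#' @param dialect \code{"tsv"} (default) or \code{"gct"}.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(counts, path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  validate_counts(counts)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "gct") {
    writeLines(c("#1.2", paste(nrow(counts), ncol(counts), sep = "\t")), con)
    header <- c("NAME", "Description", colnames(counts))
    body <- cbind(rownames(counts), "na", format(counts, trim = TRUE,
                                                 scientific = FALSE))
  } else {
    header <- c("NAME", colnames(counts))
    body <- cbind(rownames(counts), format(counts, trim = TRUE,
                                           scientific = FALSE))
  }
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a GMT gene set collection
#'
#' Each line holds a set name, a description, and one or more gene
#' identifiers, tab-separated. Duplicate genes within a line are dropped
#' (first occurrence kept); duplicate set names are an error.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (one per set), with a
#'   \code{"description"} attribute holding the per-set description lines.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    sets <- structure(list(), names = character())
    attr(sets, "description") <- character()
    return(sets)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1L],
         " has fewer than 3 tab-separated fields")
  nm <- vapply(fields, `[[`, "", 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate gene set name(s) in GMT: ", paste(dup, collapse = ", "))
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(desc, nm)
  sets
}

#' Write a gene set collection in GMT format
#'
#' @param sets Named list of character vectors; an optional
#'   \code{"description"} attribute supplies the second field (default "na").
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read two-class phenotype labels in CLS format
#'
#' The CLS format has a header line \code{"<n> 2 1"}, a class-name line
#' beginning with \code{#}, and an assignment line of \code{n} tokens. Tokens
#' may be the class names themselves or 0/1 indices into the class-name line.
#' Assignments are positional: the i-th token labels the i-th column of the
#' count matrix.
#'
#' @param path Path to the CLS file.
#' @return A factor of length \code{n} whose levels are the two class names
#'   in the order of the class-name line (first level = reference class).
#' @export
read_cls <- function(path) {
  if (!file.exists(path)) stop("CLS file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) stop("CLS file must have 3 lines: ", path)
  hdr <- strsplit(lines[1L], "[ \t]+")[[1L]]
  n <- as.integer(hdr[1L]); k <- as.integer(hdr[2L])
  if (is.na(n) || is.na(k)) stop("malformed CLS header: ", lines[1L])
  if (k != 2L) stop("CLS must declare exactly 2 classes, found ", k)
  cls_line <- strsplit(sub("^#\\s*", "", lines[2L]), "[ \t]+")[[1L]]
  if (length(cls_line) != 2L)
    stop("CLS class-name line must name exactly 2 classes, found ",
         length(cls_line))
  tok <- strsplit(lines[3L], "[ \t]+")[[1L]]
  if (length(tok) != n)
    stop("CLS assignment line has ", length(tok), " tokens, header says ", n)
  if (all(tok %in% cls_line)) {
    f <- factor(tok, levels = cls_line)
  } else if (all(tok %in% c("0", "1"))) {
    f <- factor(cls_line[as.integer(tok) + 1L], levels = cls_line)
  } else {
    stop("CLS assignments must be class names or 0/1 indices")
  }
  validate_labels(f)
  f
}

#' Validate phenotype labels
#'
#' @param labels Factor with exactly two levels; each class needs at least
#'   two samples (class standard deviations are otherwise undefined).
#' @return The factor, invisibly, if valid.
#' @export
validate_labels <- function(labels) {
  if (!is.factor(labels)) stop("labels must be a factor")
  if (nlevels(labels) != 2L)
    stop("labels must have exactly 2 classes, found ", nlevels(labels))
  counts <- table(labels)
  if (any(counts < 2L))
    stop("each phenotype class needs at least 2 samples; class sizes: ",
         paste(counts, collapse = ", "))
  invisible(labels)
}

#' Write two-class phenotype labels in CLS format
#'
#' @param labels Two-level factor (see \code{\link{read_cls}}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_cls <- function(labels, path) {
  validate_labels(labels)
  writeLines(c(paste(length(labels), 2, 1),
               paste("#", paste(levels(labels), collapse = " ")),
               paste(as.integer(labels) - 1L, collapse = " ")), path)
  invisible(path)
}

.result_cols <- c("NAME", "SIZE", "AS", "NAS", "PVALUE", "FDR", "FWER")

#' Sort a result table
#'
#' Orders rows by FDR ascending, ties broken by NAS extremity (larger
#' \code{|NAS|} first), residual ties by set name for determinism.
#'
#' @param table Result data frame with columns NAME, SIZE, AS, NAS, PVALUE,
#'   FDR, FWER.
#' @return The reordered data frame.
#' @export
sort_results <- function(table) {
  stopifnot(all(.result_cols %in% names(table)))
  table[order(table$FDR, -abs(table$NAS), table$NAME), , drop = FALSE]
}

#' Write a gene set association result table
#'
#' Writes a tab-delimited file with header
#' \code{NAME SIZE AS NAS P-VALUE FDR FWER}, rows in sorted order
#' (\code{\link{sort_results}}).
#'
#' @param table Result data frame (in-memory column PVALUE maps to the
#'   P-VALUE file column).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(table, path) {
  table <- sort_results(table)
  out <- table[, .result_cols]
  names(out) <- c("NAME", "SIZE", "AS", "NAS", "P-VALUE", "FDR", "FWER")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by \code{\link{write_results}}
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns NAME, SIZE, AS, NAS, PVALUE, FDR, FWER.
#' @export
read_results <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  names(tab)[names(tab) == "P-VALUE"] <- "PVALUE"
  stopifnot(all(.result_cols %in% names(tab)))
  tab
}
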