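#' Read a one-to-one ortholog table
#'
#' Tab-separated, two columns (`gene_a`, `gene_b`), header optional but
#' recommended. One-to-one: no gene may appear twice in either column.
#'
#' @param path TSV file.
#' @return data.frame (`OrthologTable`) with `gene_a`, `gene_b`.
#' @export
read_ortholog_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  ortholog_table(tab[[1L]], tab[[2L]])
}

#' Construct a one-to-one ortholog table
#'
#' @param gene_a,gene_b equal-length symbol vectors; no duplicates within a
#'   column.
#' @return data.frame with class `OrthologTable`.
#' @export
ortholog_table <- function(gene_a, gene_b) {
  if (anyDuplicated(gene_a) || anyDuplicated(gene_b))
    stop("ortholog mapping must be one-to-one")
  structure(data.frame(gene_a = gene_a, gene_b = gene_b,
                       stringsAsFactors = FALSE),
            class = c("OrthologTable", "data.frame"))
}

#' Restrict two matrices to their shared ortholog gene space
#'
#' Reindexes both normalized matrices to the ortholog pairs present in both
#' (matrix b's genes are renamed to their a-side symbols), in identical
#' order.
#'
#' @param norm_a,norm_b [normalize_counts()] results for the two species.
#' @param table an [ortholog_table()] (`gene_a` in `norm_a`'s universe,
#'   `gene_b` in `norm_b`'s).
#' @param min_shared minimum shared genes required (default 50).
#' @return list with reindexed `a` and `b`.
#' @export
restrict_to_orthologs <- function(norm_a, norm_b, table, min_shared = 50L) {
  stopifnot(inherits(table, "OrthologTable"))
  keep <- table$gene_a %in% norm_a$gene_ids & table$gene_b %in% norm_b$gene_ids
  if (sum(keep) < min_shared)
    stop("too few shared ortholog genes: ", sum(keep), " < ", min_shared)
  tab <- table[keep, , drop = FALSE]
  sub <- function(norm, genes, new_names) {
    norm$values <- norm$values[genes, , drop = FALSE]
    rownames(norm$values) <- new_names
    norm$gene_ids <- new_names
    norm
  }
  list(a = sub(norm_a, tab$gene_a, tab$gene_a),
       b = sub(norm_b, tab$gene_b, tab$gene_a))
}

#' Band label for a correlation coefficient
#'
#' The banding convention of the cross-species map: `low` below 0.3, `mid`
#' in \[0.3, 0.5\], `high` above 0.5.
#'
#' @param r numeric vector of correlations in \[-1, 1\].
#' @return character vector of band labels.
#' @export
correlation_band <- function(r) {
  stopifnot(all(r >= -1 & r <= 1, na.rm = TRUE))
  ifelse(r < 0.3, "low", ifelse(r <= 0.5, "mid", "high"))
}

#' Cross-species cell-type centroid correlation
#'
#' Spearman (default) correlation between cell-type centroid profiles (mean
#' normalized expression over the shared ortholog gene space), with the
#' 0.3/0.5 band labels attached.
#'
#' @param norm_a,norm_b ortholog-aligned matrices from
#'   [restrict_to_orthologs()] (same genes, same order).
#' @param annot_a,annot_b `CellAnnotation`s for the two datasets (>= 2 cell
#'   types each; types with fewer than 3 cells are an error).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return object of class `CorrelationMap`: list with `r` (types_a x
#'   types_b correlation matrix) and `band` (same shape, labels).
#' @export
celltype_correlation <- function(norm_a, annot_a, norm_b, annot_b,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!identical(norm_a$gene_ids, norm_b$gene_ids))
    stop("matrices must share an aligned gene space; see restrict_to_orthologs()")
  centroid <- function(norm, annot) {
    ann <- annot$cells[match(norm$cell_ids, annot$cells$barcode), ]
    sizes <- table(ann$cell_type)
    if (length(sizes) < 2L) stop("need at least 2 cell types per side")
    small <- names(sizes)[sizes < 3L]
    if (length(small))
      stop("cell type(s) with < 3 cells: ", paste(small, collapse = ", "))
    pseudobulk(norm, ann$cell_type)
  }
  ca <- centroid(norm_a, annot_a)
  cb <- centroid(norm_b, annot_b)
  r <- stats::cor(ca, cb, method = method)
  structure(list(r = r, band = matrix(correlation_band(r), nrow(r), ncol(r),
                                      dimnames = dimnames(r))),
            class = "CorrelationMap")
}

#' @export
print.CorrelationMap <- function(x, ...) {
  cat("CorrelationMap:", nrow(x$r), "x", ncol(x$r), "cell types\n")
  print(round(x$r, 3))
  invisible(x)
}
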