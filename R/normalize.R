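#' Depth-normalize and log-transform counts
#'
#' Standard droplet-data normalization: counts are rescaled to a common
#' library size (`scale_total`, counts-per-10,000 by default) and
#' log-transformed with a pseudocount of one on the natural scale, i.e.
#' `value(g, c) = log(1 + count(g, c) * scale_total / libsize(c))`.
#'
#' @param x a [cell_matrix()].
#' @param scale_total target library size; default 1e4.
#' @return object of class `NormalizedMatrix`: list with `values` (sparse
#'   genes x cells, all >= 0), `scale_total`, `gene_ids`, `cell_ids`, and the
#'   per-cell `meta` (and `truth`) carried over from `x`.
#' @export
normalize_counts <- function(x, scale_total = 1e4) {
  validate_cell_matrix(x)
  lib <- Matrix::colSums(x$counts)
  if (any(lib == 0))
    stop("cell(s) with zero library size: ",
         paste(utils::head(x$cell_ids[lib == 0], 5), collapse = ", "))
  vals <- x$counts %*% Matrix::Diagonal(x = scale_total / lib)
  vals <- methods::as(vals, "CsparseMatrix")
  vals@x <- log1p(vals@x)
  dimnames(vals) <- dimnames(x$counts)
  structure(
    list(values = vals, scale_total = scale_total,
         gene_ids = x$gene_ids, cell_ids = x$cell_ids,
         meta = x$meta, truth = x$truth),
    class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d genes x %d cells (log1p CP%g)\n",
              nrow(x$values), ncol(x$values), x$scale_total))
  invisible(x)
}

#' Per-group mean expression profiles (pseudobulk)
#'
#' Averages normalized expression over groups of cells, e.g. per donor or
#' per cluster, yielding one column per group.
#'
#' @param norm a [normalize_counts()] result.
#' @param group either the name of a metadata column or a vector of group
#'   labels, one per cell.
#' @return dense matrix, genes x groups, of group means.
#' @export
pseudobulk <- function(norm, group) {
  if (length(group) == 1L && is.character(group)) {
    if (!group %in% names(norm$meta))
      stop("unknown metadata key: ", group)
    group <- norm$meta[[group]]
  }
  if (length(group) != ncol(norm$values))
    stop("group must have one label per cell")
  group <- as.character(group)
  levels <- sort(unique(group))
  out <- matrix(0, nrow(norm$values), length(levels),
                dimnames = list(norm$gene_ids, levels))
  for (g in levels) {
    idx <- which(group == g)
    out[, g] <- Matrix::rowSums(norm$values[, idx, drop = FALSE]) / length(idx)
  }
  out
}

# Per-gene fraction of cells with nonzero expression, by column index set.
frac_detected <- function(values, idx) {
  n <- length(idx)
  if (n == 0L) return(numeric(nrow(values)))
  Matrix::rowSums(values[, idx, drop = FALSE] > 0) / n
}

# Mean of expm1(values) per gene over a column index set (linear scale).
linear_mean <- function(values, idx) {
  v <- values[, idx, drop = FALSE]
  v@x <- expm1(v@x)
  Matrix::rowSums(v) / length(idx)
}
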