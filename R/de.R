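# Vectorized two-sided Wilcoxon rank-sum test applied gene-wise.
#
# Normal approximation with tie correction and continuity correction —
# the regime here is always many cells per group, where the approximation
# is standard. Works on a sparse genes x cells slice; genes are processed
# in chunks to bound the dense working set.
ranksum_pvalues <- function(values, idx_a, idx_b, chunk = 200L) {
  n_a <- length(idx_a); n_b <- length(idx_b); n <- n_a + n_b
  if (n_a < 1L || n_b < 1L) stop("both groups must be non-empty")
  p <- numeric(nrow(values))
  cols <- c(idx_a, idx_b)
  for (start in seq(1L, nrow(values), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(values))
    m <- as.matrix(values[rows, cols, drop = FALSE])
    p[rows] <- apply(m, 1L, function(v) {
      r <- rank(v)
      w <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2  # Mann-Whitney U
      ties <- table(r)  # tie groups from ranks, not floating-point values
      sigma2 <- (n_a * n_b / 12) *
        ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
      if (sigma2 <= 0) return(1)
      z <- w - n_a * n_b / 2
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      2 * stats::pnorm(-abs(z))
    })
  }
  p
}

#' Differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test on normalized expression with
#' Benjamini-Hochberg correction. Genes enter the test when detected in at
#' least `min_frac` of the cells of at least one group. The log2 fold change
#' is computed on de-logged group means with a pseudocount of 1 on the
#' linear scale, so it is finite for genes absent from one group.
#'
#' @param norm a [normalize_counts()] result.
#' @param cells_a,cells_b barcodes or column indices of the two groups
#'   (>= 3 cells each).
#' @param min_frac detection-fraction filter, default 0.10.
#' @return data.frame (`DETable`) with columns `gene`, `group_a_mean`,
#'   `group_b_mean`, `log2_fold_change`, `p_value`, `fdr`, `frac_expr_a`,
#'   `frac_expr_b`. Means are on the linear (de-logged) scale.
#' @export
differential_expression <- function(norm, cells_a, cells_b, min_frac = 0.10) {
  idx_a <- resolve_cells(norm, cells_a)
  idx_b <- resolve_cells(norm, cells_b)
  if (length(idx_a) < 3L || length(idx_b) < 3L)
    stop("both groups must have at least 3 cells")
  fa <- frac_detected(norm$values, idx_a)
  fb <- frac_detected(norm$values, idx_b)
  keep <- which(fa >= min_frac | fb >= min_frac)
  if (!length(keep)) stop("no gene passes the expression filter")
  ma <- linear_mean(norm$values, idx_a)[keep]
  mb <- linear_mean(norm$values, idx_b)[keep]
  p <- ranksum_pvalues(norm$values[keep, , drop = FALSE], idx_a, idx_b)
  data.frame(
    gene = norm$gene_ids[keep],
    group_a_mean = ma,
    group_b_mean = mb,
    log2_fold_change = log2((ma + 1) / (mb + 1)),
    p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    frac_expr_a = fa[keep],
    frac_expr_b = fb[keep],
    stringsAsFactors = FALSE)
}

# Map barcodes (character) or indices (numeric/logical) to column indices.
resolve_cells <- function(norm, cells) {
  if (is.character(cells)) {
    idx <- match(cells, norm$cell_ids)
    if (anyNA(idx))
      stop("unknown barcode(s): ",
           paste(utils::head(cells[is.na(idx)], 5), collapse = ", "))
    idx
  } else if (is.logical(cells)) {
    which(cells)
  } else {
    as.integer(cells)
  }
}
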