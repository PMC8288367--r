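# Per-gene variance across cells of a sparse matrix, without densifying.
rowVars_sparse <- function(v) {
  mu <- Matrix::rowMeans(v)
  v2 <- v
  v2@x <- v2@x^2
  n <- ncol(v)
  pmax((Matrix::rowSums(v2) - n * mu^2) / max(n - 1L, 1L), 0)
}

#' Most variable genes of a normalized matrix
#'
#' Genes ranked by variance of normalized expression across cells; the
#' usual feature-selection step before clustering or cross-dataset
#' comparison.
#'
#' @param norm a [normalize_counts()] result.
#' @param n how many genes to return.
#' @return character vector of gene symbols, most variable first.
#' @export
variable_genes <- function(norm, n = 2000L) {
  v <- rowVars_sparse(norm$values)
  norm$gene_ids[order(v, decreasing = TRUE)[seq_len(min(n, length(v)))]]
}

#' Default marker panel
#'
#' Positive markers for the major retinal classes used by the generator and
#' annotation examples, plus the H1/H2 horizontal-cell subtype rules
#' (H1: LHX1, PCP4; H2: ISL1, CALB1).
#'
#' @return object of class `MarkerPanel`: list with `entries` (cell type ->
#'   markers) and `subtype_rules` (cell type -> subtype -> positive/negative
#'   markers).
#' @export
default_marker_panel <- function() {
  marker_panel(
    entries = list(
      rod = c("NRL", "RHO", "GNGT1", "CNGA1"),
      cone = c("ARR3", "PDE6H", "GNAT2", "OPN1SW"),
      HC = c("ONECUT1", "ONECUT2"),
      BC = c("VSX2", "TRPM1", "GRM6"),
      MG = c("RLBP1", "GLUL", "APOE", "SLC1A3"),
      AC = c("GAD1", "SLC6A9", "TFAP2A"),
      microglia = c("AIF1", "C1QA", "CX3CR1")),
    subtype_rules = list(
      HC = list(H1 = list(positive = c("LHX1", "PCP4"), negative = c("ISL1", "CALB1")),
                H2 = list(positive = c("ISL1", "CALB1"), negative = c("LHX1", "PCP4")))))
}

#' Construct and validate a marker panel
#'
#' @param entries named list: cell type -> character vector of positive markers.
#' @param subtype_rules named list: cell type -> subtype -> list with
#'   `positive` (and optionally `negative`) marker vectors. Subtypes may only
#'   be defined for cell types present in `entries`.
#' @return object of class `MarkerPanel`.
#' @export
marker_panel <- function(entries, subtype_rules = list()) {
  if (!length(entries)) stop("empty marker panel")
  for (ct in names(entries))
    if (!length(entries[[ct]]) || any(!nzchar(entries[[ct]])))
      stop("empty marker symbol for cell type ", ct)
  orphan <- setdiff(names(subtype_rules), names(entries))
  if (length(orphan))
    stop("subtype rules for absent cell type(s): ", paste(orphan, collapse = ", "))
  structure(list(entries = entries, subtype_rules = subtype_rules),
            class = "MarkerPanel")
}

#' Read a marker panel from YAML
#'
#' Schema: top-level `entries` (cell type -> marker list) and optional
#' `subtype_rules` (cell type -> subtype -> positive/negative lists).
#'
#' @param path YAML file.
#' @return a [marker_panel()].
#' @export
read_marker_panel <- function(path) {
  y <- yaml::read_yaml(path)
  marker_panel(entries = lapply(y$entries, unlist),
               subtype_rules = lapply(y$subtype_rules, function(ct)
                 lapply(ct, function(s) lapply(s, unlist))))
}

#' Cluster cells by community detection in PCA space
#'
#' The conventional droplet pipeline: selection of the most variable genes,
#' per-gene z-scaling, top principal components, a k-nearest-neighbour
#' graph and Louvain community detection. Deterministic under a fixed seed.
#' Intended for the moderate cell numbers used here (the exact k-NN search
#' is quadratic in cells).
#'
#' @param norm a [normalize_counts()] result with >= 50 cells.
#' @param n_neighbors k for the k-NN graph (default 15).
#' @param resolution Louvain resolution (default 1.0).
#' @param n_pcs number of principal components (default 30).
#' @param n_hvg number of highly variable genes kept before PCA (default
#'   2000; all genes when fewer are present).
#' @param seed integer seed.
#' @return integer vector of cluster ids (1-based), one per cell.
#' @export
cluster_cells <- function(norm, n_neighbors = 15L, resolution = 1.0,
                          n_pcs = 30L, n_hvg = 2000L, seed = 1L) {
  n <- ncol(norm$values)
  if (n < 50L) stop("need at least 50 cells to cluster")
  gene_var <- rowVars_sparse(norm$values)
  informative <- gene_var > 1e-10  # tolerance absorbs sparse-arithmetic residue
  if (!any(informative)) stop("degenerate input: all cells identical")
  hvg <- order(gene_var, decreasing = TRUE)[seq_len(min(n_hvg, sum(informative)))]
  x <- as.matrix(Matrix::t(norm$values[hvg, , drop = FALSE]))
  x <- scale(x)
  n_pcs <- min(n_pcs, ncol(x) - 1L, n - 1L)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  pcs <- stats::prcomp(x, rank. = n_pcs, center = FALSE)$x
  d <- as.matrix(stats::dist(pcs))
  k <- min(n_neighbors, n - 1L)
  nn <- apply(d, 1L, function(row) order(row)[2:(k + 1L)])
  edges <- cbind(rep(seq_len(n), each = k), as.vector(nn))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(comm))
}

#' Score clusters against a marker panel and annotate cells
#'
#' Per gene, cluster-mean expression is z-scored across clusters; a
#' cluster's score for a cell type is the mean z over that type's panel
#' markers, and the cluster is labeled by the argmax. Cells inherit their
#' cluster's label; per-cluster score vectors are retained for audit. Ties
#' are broken lexicographically on the type name and flagged.
#'
#' @param norm a [normalize_counts()] result.
#' @param clusters per-cell cluster ids, e.g. from [cluster_cells()].
#' @param panel a [marker_panel()]; markers absent from the matrix are
#'   dropped with a warning (error if a type loses all its markers).
#' @return object of class `CellAnnotation`: list with `cells` (data.frame
#'   `barcode`, `cluster_id`, `cell_type`, `subtype`, `tie_flag`),
#'   `cluster_scores` (cluster x type matrix) and `panel`.
#' @export
score_cell_types <- function(norm, clusters, panel) {
  stopifnot(inherits(panel, "MarkerPanel"))
  entries <- lapply(panel$entries, function(mk) mk[mk %in% norm$gene_ids])
  dropped <- sum(lengths(panel$entries)) - sum(lengths(entries))
  if (dropped > 0)
    warning(dropped, " marker(s) absent from the matrix were dropped")
  dead <- names(entries)[lengths(entries) == 0L]
  if (length(dead))
    stop("all markers missing for type(s): ", paste(dead, collapse = ", "))
  cm <- pseudobulk(norm, as.character(clusters))
  mk_all <- unique(unlist(entries))
  z <- t(scale(t(cm[mk_all, , drop = FALSE])))
  z[is.na(z)] <- 0  # constant genes carry no signal
  scores <- vapply(entries, function(mk)
    colMeans(z[mk, , drop = FALSE]), numeric(ncol(cm)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = ncol(cm),
                                             dimnames = list(colnames(cm), names(entries)))
  best <- apply(scores, 1L, function(s) {
    top <- names(s)[s == max(s)]
    c(label = sort(top)[1L], tie = as.character(length(top) > 1L))
  })
  lab_by_cluster <- stats::setNames(as.character(best["label", ]), colnames(best))
  tie_by_cluster <- stats::setNames(as.logical(best["tie", ]), colnames(best))
  lab <- lab_by_cluster[as.character(clusters)]
  tie <- tie_by_cluster[as.character(clusters)]
  ann <- data.frame(barcode = norm$cell_ids,
                    cluster_id = as.integer(factor(as.character(clusters),
                                                   levels = colnames(cm))),
                    cell_type = unname(lab),
                    subtype = NA_character_,
                    tie_flag = tie,
                    stringsAsFactors = FALSE)
  structure(list(cells = ann, cluster_scores = scores, panel = panel),
            class = "CellAnnotation")
}

#' @export
print.CellAnnotation <- function(x, ...) {
  tab <- table(x$cells$cell_type)
  cat("CellAnnotation:", nrow(x$cells), "cells\n")
  print(tab)
  invisible(x)
}

#' Build a CellAnnotation from generator ground truth
#'
#' Convenience for recovery experiments that exercise one downstream stage
#' in isolation: cells are labeled with their true types (subtypes are NOT
#' carried over — subtype classifiers start from scratch).
#'
#' @param mat a [cell_matrix()] carrying `truth`.
#' @return a `CellAnnotation`.
#' @export
annotation_from_truth <- function(mat) {
  if (is.null(mat$truth)) stop("matrix carries no ground truth")
  tr <- mat$truth[match(mat$cell_ids, mat$truth$barcode), ]
  ann <- data.frame(barcode = mat$cell_ids,
                    cluster_id = as.integer(factor(tr$cell_type)),
                    cell_type = tr$cell_type,
                    subtype = NA_character_,
                    tie_flag = FALSE,
                    stringsAsFactors = FALSE)
  structure(list(cells = ann, cluster_scores = NULL,
                 panel = default_marker_panel()),
            class = "CellAnnotation")
}

#' Classify rod subtypes by transcript positivity
#'
#' Each annotated rod is labeled `MYO9A+` when the transcript is detected
#' (raw count >= 1, equivalently normalized value > 0) and `MYO9A-`
#' otherwise. Non-rod cells are untouched.
#'
#' @param norm a [normalize_counts()] result.
#' @param annot a `CellAnnotation` containing rods.
#' @param gene splitting gene, default `"MYO9A"`.
#' @param cell_type which annotated type to split, default `"rod"`.
#' @return the annotation with rod `subtype` filled in.
#' @export
classify_rod_subtype <- function(norm, annot, gene = "MYO9A",
                                 cell_type = "rod") {
  if (!gene %in% norm$gene_ids) stop("gene absent: ", gene)
  cells <- annot$cells
  rods <- which(cells$cell_type == cell_type)
  if (!length(rods)) stop("annotation contains no ", cell_type, " cells")
  idx <- match(cells$barcode[rods], norm$cell_ids)
  pos <- as.vector(norm$values[gene, idx, drop = FALSE]) > 0
  cells$subtype[rods] <- ifelse(pos, paste0(gene, "+"), paste0(gene, "-"))
  annot$cells <- cells
  annot
}

#' Classify horizontal-cell subtypes by marker scores
#'
#' Per annotated HC, the H1 score is the mean z-scored expression (across
#' HCs) of the H1 positive markers and likewise for H2; the cell is labeled
#' by the argmax, with lexicographic tie-breaking (H1) and a flag.
#'
#' @param norm a [normalize_counts()] result.
#' @param annot a `CellAnnotation` containing HCs.
#' @param cell_type annotated type holding horizontal cells, default `"HC"`.
#' @return the annotation with HC `subtype` filled in.
#' @export
classify_hc_subtype <- function(norm, annot, cell_type = "HC") {
  rules <- annot$panel$subtype_rules[[cell_type]]
  if (is.null(rules)) stop("no subtype rules for cell type ", cell_type)
  cells <- annot$cells
  hcs <- which(cells$cell_type == cell_type)
  if (!length(hcs)) stop("annotation contains no ", cell_type, " cells")
  idx <- match(cells$barcode[hcs], norm$cell_ids)
  genes <- unique(unlist(lapply(rules, `[[`, "positive")))
  absent <- setdiff(genes, norm$gene_ids)
  if (length(absent)) stop("rule gene(s) absent: ", paste(absent, collapse = ", "))
  x <- as.matrix(norm$values[genes, idx, drop = FALSE])
  z <- t(scale(t(x)))
  z[is.na(z)] <- 0
  scores <- vapply(rules, function(r)
    colMeans(z[r$positive, , drop = FALSE]), numeric(length(hcs)))
  subtypes <- sort(names(rules))
  scores <- scores[, subtypes, drop = FALSE]
  pick <- apply(scores, 1L, function(s) which(s == max(s))[1L])
  tie <- apply(scores, 1L, function(s) sum(s == max(s)) > 1L)
  cells$subtype[hcs] <- subtypes[pick]
  cells$tie_flag[hcs] <- cells$tie_flag[hcs] | tie
  annot$cells <- cells
  annot
}

#' Subset a CellAnnotation to a set of cells
#'
#' @param annot a `CellAnnotation`.
#' @param keep logical vector over annotation rows, or barcodes.
#' @return the filtered `CellAnnotation`.
#' @export
subset_annotation <- function(annot, keep) {
  if (is.character(keep)) keep <- annot$cells$barcode %in% keep
  annot$cells <- annot$cells[keep, , drop = FALSE]
  rownames(annot$cells) <- NULL
  annot
}

#' Estimate label proportions with bootstrap confidence intervals
#'
#' Within each metadata group, the proportion of each label with a
#' percentile bootstrap 95% CI from resampling cells within the group.
#'
#' @param annot a `CellAnnotation`.
#' @param meta per-cell metadata (rows matched to annotation barcodes).
#' @param group_keys metadata column names defining groups (e.g.
#'   `c("region", "stage")`); may be empty for a single group.
#' @param label_col which annotation column to tabulate: `"cell_type"`
#'   (default) or `"subtype"`.
#' @param n_boot bootstrap replicates (>= 200).
#' @param seed integer seed.
#' @return data.frame (`ProportionTable`): `group`, `label`, `count`,
#'   `proportion`, `ci_low`, `ci_high`.
#' @export
estimate_proportions <- function(annot, meta, group_keys, label_col = "cell_type",
                                 n_boot = 500L, seed = 1L) {
  if (n_boot < 200L) stop("n_boot must be at least 200")
  miss <- setdiff(group_keys, names(meta))
  if (length(miss)) stop("unknown group key(s): ", paste(miss, collapse = ", "))
  cells <- annot$cells
  m <- meta[match(cells$barcode, meta$barcode), , drop = FALSE]
  labels <- cells[[label_col]]
  keep <- !is.na(labels)
  labels <- labels[keep]; m <- m[keep, , drop = FALSE]
  grp <- if (length(group_keys))
    do.call(paste, c(m[group_keys], sep = "|")) else rep("all", length(labels))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  out <- list()
  for (g in sort(unique(grp))) {
    lab_g <- labels[grp == g]
    n <- length(lab_g)
    if (n == 0L) stop("empty group: ", g)
    levs <- sort(unique(lab_g))
    counts <- table(factor(lab_g, levels = levs))
    boot <- matrix(0, n_boot, length(levs))
    for (b in seq_len(n_boot))
      boot[b, ] <- tabulate(factor(sample(lab_g, n, replace = TRUE),
                                   levels = levs), length(levs)) / n
    ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975))
    prop <- as.numeric(counts) / n
    out[[g]] <- data.frame(group = g, label = levs,
                           count = as.integer(counts),
                           proportion = prop,
                           ci_low = pmin(ci[1L, ], prop),
                           ci_high = pmax(ci[2L, ], prop),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Co-positivity query
#'
#' Fraction (and barcodes) of cells of one annotated type detected for every
#' gene in a small set — e.g. the OTX2+RLBP1+ co-positive population.
#'
#' @param norm a [normalize_counts()] result.
#' @param annot a `CellAnnotation`.
#' @param genes genes that must all be detected (count >= 1).
#' @param cell_type restrict to one annotated type; `NULL` = all cells.
#' @return list with `fraction` and `barcodes`.
#' @export
co_positive <- function(norm, annot, genes, cell_type = NULL) {
  absent <- setdiff(genes, norm$gene_ids)
  if (length(absent)) stop("gene(s) absent: ", paste(absent, collapse = ", "))
  cells <- annot$cells
  if (!is.null(cell_type)) cells <- cells[cells$cell_type == cell_type, ]
  idx <- match(cells$barcode, norm$cell_ids)
  hit <- Matrix::colSums(norm$values[genes, idx, drop = FALSE] > 0) == length(genes)
  list(fraction = mean(hit), barcodes = cells$barcode[hit])
}
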