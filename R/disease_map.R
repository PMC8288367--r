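#' Read a disease-gene table
#'
#' Tab-separated with header, columns `disease` and `gene` (the layout of a
#' retinal-disease gene catalogue export). Duplicate (disease, gene) pairs
#' are rejected.
#'
#' @param path TSV file.
#' @return data.frame (`DiseaseGeneTable`) with `disease`, `gene`.
#' @export
read_disease_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  disease_gene_table(tab$disease, tab$gene)
}

#' Construct a disease-gene table
#'
#' @param disease,gene equal-length character vectors.
#' @return data.frame with class `DiseaseGeneTable`.
#' @export
disease_gene_table <- function(disease, gene) {
  if (!length(disease)) stop("empty disease table")
  if (anyDuplicated(paste(disease, gene, sep = "\r")))
    stop("duplicate (disease, gene) pairs")
  structure(data.frame(disease = disease, gene = gene, stringsAsFactors = FALSE),
            class = c("DiseaseGeneTable", "data.frame"))
}

# Gene x group matrix of mean normalized expression, z-scaled per gene
# across groups. Groups are cell_type|region (or any label vector).
group_z_profile <- function(norm, group_labels) {
  gm <- pseudobulk(norm, group_labels)
  z <- t(scale(t(gm)))
  z[is.na(z)] <- 0  # genes flat across groups carry no specificity
  z
}

celltype_region_groups <- function(norm, annot) {
  ann <- annot$cells[match(norm$cell_ids, annot$cells$barcode), ]
  paste(ann$cell_type, norm$meta$region, sep = "|")
}

#' Aggregate disease-gene expression by cell type and region
#'
#' Per gene, mean normalized expression per (cell type, region) group is
#' z-scaled across groups; a disease's score in a group is the mean z over
#' the disease's genes present in the matrix — comparable across diseases of
#' different set sizes. Diseases with no present gene are returned with
#' `NA` scores and `n_genes = 0`.
#'
#' @param norm a [normalize_counts()] result.
#' @param annot a `CellAnnotation`.
#' @param disease_table a [disease_gene_table()].
#' @return data.frame with `disease`, `group` (cell_type|region), `score`,
#'   `n_genes` (present genes used).
#' @export
aggregate_disease_score <- function(norm, annot, disease_table) {
  stopifnot(inherits(disease_table, "DiseaseGeneTable"))
  z <- group_z_profile(norm, celltype_region_groups(norm, annot))
  if (!any(disease_table$gene %in% rownames(z)))
    stop("no disease gene present in the matrix")
  sets <- split(disease_table$gene, disease_table$disease)
  out <- list()
  for (d in names(sets)) {
    genes <- intersect(sets[[d]], rownames(z))
    score <- if (length(genes)) colMeans(z[genes, , drop = FALSE]) else
      stats::setNames(rep(NA_real_, ncol(z)), colnames(z))
    out[[d]] <- data.frame(disease = d, group = colnames(z),
                           score = unname(score), n_genes = length(genes),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bootstrap gene-set enrichment p-value for one score
#'
#' Null scores are built from `n_boot` random gene sets of the same size
#' drawn from the expressed genes; `p = (1 + #(null >= observed)) / (n_boot
#' + 1)`, so p is bounded below by `1/(n_boot + 1)`.
#'
#' @param observed the observed aggregate score of the disease set in the
#'   group of interest.
#' @param z_column that group's per-gene z profile (named vector over genes,
#'   as one column of the matrix behind [aggregate_disease_score()]).
#' @param expressed_genes pool to resample from (genes detected in the
#'   dataset); must contain at least `set_size` genes.
#' @param set_size disease set size to match.
#' @param n_boot bootstrap replicates (>= 200).
#' @param seed integer seed.
#' @return numeric p-value in (0, 1].
#' @export
bootstrap_test <- function(observed, z_column, expressed_genes, set_size,
                           n_boot = 1000L, seed = 1L) {
  if (n_boot < 200L) stop("n_boot must be at least 200")
  pool <- intersect(expressed_genes, names(z_column))
  if (length(pool) < set_size)
    stop("fewer expressed genes than the disease set size")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  null <- vapply(seq_len(n_boot), function(b)
    mean(z_column[sample(pool, set_size)]), 0)
  (1 + sum(null >= observed)) / (n_boot + 1)
}

#' Disease-map enrichment across all (disease, group) pairs
#'
#' Runs [aggregate_disease_score()] and attaches a bootstrap p-value per row
#' plus Benjamini-Hochberg adjustment across all rows.
#'
#' @inheritParams aggregate_disease_score
#' @param n_boot bootstrap replicates per row (default 1000).
#' @param seed integer seed.
#' @param min_frac detection fraction defining "expressed" pool members
#'   (default 0.05 across all cells).
#' @return data.frame (`EnrichmentResult`): `disease`, `group`, `score`,
#'   `n_genes`, `p`, `fdr`, `n_boot`.
#' @export
bootstrap_enrichment <- function(norm, annot, disease_table, n_boot = 1000L,
                                 seed = 1L, min_frac = 0.05) {
  scores <- aggregate_disease_score(norm, annot, disease_table)
  z <- group_z_profile(norm, celltype_region_groups(norm, annot))
  expressed <- norm$gene_ids[
    frac_detected(norm$values, seq_len(ncol(norm$values))) >= min_frac]
  scores$p <- NA_real_
  ok <- which(!is.na(scores$score))
  for (r in ok) {
    scores$p[r] <- bootstrap_test(
      scores$score[r], z[, scores$group[r]], expressed,
      set_size = scores$n_genes[r], n_boot = n_boot,
      seed = seed + r)  # row-specific stream, reproducible from `seed`
  }
  scores$fdr <- stats::p.adjust(scores$p, method = "BH")
  scores$n_boot <- as.integer(n_boot)
  scores
}

#' Aggregate disease-gene expression by age stage
#'
#' Same aggregation as [aggregate_disease_score()] with groups defined by
#' donor age stage (optionally crossed with region). Stages with no cells
#' are simply absent from the output.
#'
#' @inheritParams aggregate_disease_score
#' @param stages per-cell stage labels (defaults to staging donor ages).
#' @param by_region also split by region (default FALSE).
#' @param stage_map ordered stage definitions.
#' @return data.frame with `disease`, `group` (stage or stage|region),
#'   `score`, `n_genes`.
#' @export
disease_score_by_age <- function(norm, annot, disease_table, stages = NULL,
                                 by_region = FALSE,
                                 stage_map = default_stage_map()) {
  stopifnot(inherits(disease_table, "DiseaseGeneTable"))
  if (is.null(stages))
    stages <- vapply(norm$meta$age_years, assign_stage, "", stage_map = stage_map)
  grp <- if (by_region) paste(stages, norm$meta$region, sep = "|") else stages
  z <- group_z_profile(norm, grp)
  if (!any(disease_table$gene %in% rownames(z)))
    stop("no disease gene present in the matrix")
  sets <- split(disease_table$gene, disease_table$disease)
  out <- list()
  for (d in names(sets)) {
    genes <- intersect(sets[[d]], rownames(z))
    score <- if (length(genes)) colMeans(z[genes, , drop = FALSE]) else
      stats::setNames(rep(NA_real_, ncol(z)), colnames(z))
    out[[d]] <- data.frame(disease = d, group = colnames(z),
                           score = unname(score), n_genes = length(genes),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
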