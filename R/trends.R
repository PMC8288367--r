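#' Default donor stage map
#'
#' Three ordered age stages used throughout: adult (18-45 years), mid-age
#' (46-70) and aging (71-120), the binning under which a 35-year-old donor
#' is adult, 52- and 63-year-olds are mid-age and 86/87-year-olds are aging.
#'
#' @return data.frame (`StageMap`) with `stage_name`, `min_age`, `max_age`,
#'   ordered and non-overlapping.
#' @export
default_stage_map <- function() {
  data.frame(stage_name = c("adult", "mid-age", "aging"),
             min_age = c(18, 46, 71),
             max_age = c(45, 70, 120),
             stringsAsFactors = FALSE)
}

validate_stage_map <- function(map) {
  need <- c("stage_name", "min_age", "max_age")
  if (!all(need %in% names(map))) stop("malformed stage map")
  if (anyDuplicated(map$stage_name)) stop("stage names must be unique")
  if (any(map$min_age > map$max_age)) stop("stage interval inverted")
  o <- order(map$min_age)
  if (nrow(map) > 1L && any(map$max_age[o][-nrow(map)] >= map$min_age[o][-1L]))
    stop("stage intervals overlap")
  invisible(map)
}

#' Assign a donor age to a stage
#'
#' @param age_years non-negative age in years.
#' @param stage_map a [default_stage_map()]-shaped table.
#' @return the containing stage's name, or `"unstaged"` when the age falls
#'   outside every interval.
#' @export
assign_stage <- function(age_years, stage_map = default_stage_map()) {
  validate_stage_map(stage_map)
  if (age_years < 0) stop("age must be non-negative")
  hit <- which(age_years >= stage_map$min_age & age_years <= stage_map$max_age)
  if (!length(hit)) return("unstaged")
  stage_map$stage_name[hit[1L]]
}

#' Detect genes with monotone expression trends across age stages
#'
#' A gene is called "up" when its mean normalized expression strictly
#' increases from the first to the last stage, both adjacent stage contrasts
#' are significant (Wilcoxon rank-sum on cells pooled within stage,
#' Benjamini-Hochberg `fdr <= alpha` per contrast) and both adjacent log2
#' fold changes (de-logged means, pseudocount 1) are at least `min_log2fc`.
#' "down" is the mirror image. Genes detected in fewer than `min_frac` of
#' cells in every stage are not tested.
#'
#' @param norm a [normalize_counts()] result.
#' @param stages per-cell stage labels; defaults to staging `norm$meta$age_years`
#'   through `stage_map`.
#' @param alpha per-contrast BH threshold (default 0.05).
#' @param min_log2fc minimum adjacent |log2FC| (default 0.25).
#' @param min_frac detection filter (default 0.10).
#' @param stage_map ordered stage definitions.
#' @return data.frame (`TrendResult`): `gene`, `direction` (`up`/`down`/`none`),
#'   stage means (linear scale) as `mean_<stage>`, adjacent `log2fc_1/2` and
#'   `fdr_1/2`.
#' @export
detect_monotone_genes <- function(norm, stages = NULL, alpha = 0.05,
                                  min_log2fc = 0.25, min_frac = 0.10,
                                  stage_map = default_stage_map()) {
  validate_stage_map(stage_map)
  if (is.null(stages))
    stages <- vapply(norm$meta$age_years, assign_stage, "", stage_map = stage_map)
  stage_names <- stage_map$stage_name
  idx <- lapply(stage_names, function(s) which(stages == s))
  names(idx) <- stage_names
  empty <- stage_names[lengths(idx) == 0L]
  if (length(empty))
    stop("no cells in stage(s): ", paste(empty, collapse = ", "))

  det <- vapply(idx, function(ii) frac_detected(norm$values, ii),
                numeric(nrow(norm$values)))
  keep <- which(apply(det, 1L, max) >= min_frac)
  if (!length(keep)) stop("no gene passes the expression filter")
  vals <- norm$values[keep, , drop = FALSE]

  means <- vapply(idx, function(ii) linear_mean(vals, ii), numeric(length(keep)))
  n_adj <- length(stage_names) - 1L
  lfc <- matrix(NA_real_, length(keep), n_adj)
  fdr <- matrix(NA_real_, length(keep), n_adj)
  for (k in seq_len(n_adj)) {
    lfc[, k] <- log2((means[, k + 1L] + 1) / (means[, k] + 1))
    p <- ranksum_pvalues(vals, idx[[k + 1L]], idx[[k]])
    fdr[, k] <- stats::p.adjust(p, method = "BH")
  }
  inc <- apply(means, 1L, function(m) all(diff(m) > 0))
  dec <- apply(means, 1L, function(m) all(diff(m) < 0))
  sig <- apply(fdr <= alpha, 1L, all)
  up <- inc & sig & apply(lfc >= min_log2fc, 1L, all)
  down <- dec & sig & apply(lfc <= -min_log2fc, 1L, all)
  out <- data.frame(gene = norm$gene_ids[keep],
                    direction = ifelse(up, "up", ifelse(down, "down", "none")),
                    stringsAsFactors = FALSE)
  for (s in seq_along(stage_names))
    out[[paste0("mean_", stage_names[s])]] <- means[, s]
  for (k in seq_len(n_adj)) {
    out[[paste0("log2fc_", k)]] <- lfc[, k]
    out[[paste0("fdr_", k)]] <- fdr[, k]
  }
  out
}

#' Per-cell-type stage fold changes for a gene panel
#'
#' For each cell type and stage, the log2 fold change (pseudocount 1 on the
#' linear scale) of each gene relative to that cell type's adult-stage mean.
#' Cell types absent from a stage yield `NA`, never a silent zero.
#'
#' @param norm a [normalize_counts()] result.
#' @param annot a `CellAnnotation` (see [score_cell_types()]).
#' @param genes gene symbols to profile.
#' @param stages per-cell stage labels (defaults to staging donor ages).
#' @param stage_map ordered stage definitions; the first stage is the baseline.
#' @return 3-d array gene x cell type x stage of log2 fold changes vs the
#'   baseline stage.
#' @export
celltype_stage_foldchange <- function(norm, annot, genes, stages = NULL,
                                      stage_map = default_stage_map()) {
  validate_stage_map(stage_map)
  missing_genes <- setdiff(genes, norm$gene_ids)
  if (length(missing_genes))
    stop("gene(s) absent: ", paste(utils::head(missing_genes, 5), collapse = ", "))
  if (is.null(stages))
    stages <- vapply(norm$meta$age_years, assign_stage, "", stage_map = stage_map)
  ann <- annot$cells[match(norm$cell_ids, annot$cells$barcode), ]
  types <- sort(unique(ann$cell_type))
  stage_names <- stage_map$stage_name
  base_stage <- stage_names[1L]
  vals <- norm$values[genes, , drop = FALSE]
  out <- array(NA_real_, dim = c(length(genes), length(types), length(stage_names)),
               dimnames = list(genes, types, stage_names))
  for (ct in types) {
    base_idx <- which(ann$cell_type == ct & stages == base_stage)
    if (!length(base_idx)) next
    m0 <- linear_mean(vals, base_idx)
    for (s in stage_names) {
      idx <- which(ann$cell_type == ct & stages == s)
      if (!length(idx)) next  # stays NA: cell type missing in stage
      out[, ct, s] <- log2((linear_mean(vals, idx) + 1) / (m0 + 1))
    }
  }
  out
}
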