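#' Construct an aging gene set
#'
#' @param up_genes genes whose expression rises with age.
#' @param down_genes genes whose expression falls with age (disjoint from
#'   `up_genes`).
#' @param weights optional named vector of per-gene weights covering every
#'   listed gene; default weight 1.
#' @return object of class `AgingGeneSet`.
#' @export
aging_gene_set <- function(up_genes, down_genes = character(0), weights = NULL) {
  if (length(intersect(up_genes, down_genes)))
    stop("up and down gene lists must be disjoint")
  all_genes <- c(up_genes, down_genes)
  if (!is.null(weights)) {
    miss <- setdiff(all_genes, names(weights))
    if (length(miss))
      stop("weights missing for: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  structure(list(up_genes = up_genes, down_genes = down_genes,
                 weights = weights), class = "AgingGeneSet")
}

#' Read an aging gene set from TSV
#'
#' Accepts the export format of curated longevity/ageing gene resources:
#' tab-separated with header, columns `gene` and `direction`
#' (`up`/`down`), optional `weight`.
#'
#' @param path TSV file.
#' @return an [aging_gene_set()].
#' @export
read_aging_geneset <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  w <- if ("weight" %in% names(tab)) stats::setNames(tab$weight, tab$gene) else NULL
  aging_gene_set(up_genes = tab$gene[tab$direction == "up"],
                 down_genes = tab$gene[tab$direction == "down"],
                 weights = w)
}

# Weighted mean of per-gene z-scores (z across cells) for a gene subset.
weighted_z_mean <- function(norm, genes, weights) {
  x <- as.matrix(norm$values[genes, , drop = FALSE])
  z <- t(scale(t(x)))
  z[is.na(z)] <- 0
  w <- if (is.null(weights)) rep(1, length(genes)) else unname(weights[genes])
  as.vector(crossprod(z, w)) / sum(abs(w))
}

#' Per-cell pseudo-aging score
#'
#' Raw score = weighted mean z-scored expression over the up genes minus the
#' same over the down genes; min-max rescaled to \[0, 1\] over the dataset.
#' The rescale is order-preserving, so ranks are comparable across regions
#' and donors within one dataset.
#'
#' @param norm a [normalize_counts()] result.
#' @param gene_set an [aging_gene_set()]; at least one listed gene must be
#'   present in the matrix.
#' @return named numeric vector of per-cell scores in \[0, 1\].
#' @export
compute_aging_score <- function(norm, gene_set) {
  stopifnot(inherits(gene_set, "AgingGeneSet"))
  up <- intersect(gene_set$up_genes, norm$gene_ids)
  down <- intersect(gene_set$down_genes, norm$gene_ids)
  if (!length(up) && !length(down))
    stop("no gene-set genes present in the matrix")
  raw <- numeric(ncol(norm$values))
  if (length(up)) raw <- raw + weighted_z_mean(norm, up, gene_set$weights)
  if (length(down)) raw <- raw - weighted_z_mean(norm, down, gene_set$weights)
  rng <- range(raw)
  score <- if (diff(rng) == 0) rep(0.5, length(raw)) else
    (raw - rng[1L]) / diff(rng)
  names(score) <- norm$cell_ids
  score
}

# Local-linear (degree 1) smoother with Gaussian kernel, vectorized over a
# grid. Falls back to the weighted mean where the local design is singular.
loclin_fit <- function(x, y, grid, bandwidth) {
  vapply(grid, function(g) {
    w <- stats::dnorm((x - g) / bandwidth)
    if (sum(w) == 0) return(NA_real_)
    xc <- x - g
    sw <- sum(w); swx <- sum(w * xc); swxx <- sum(w * xc^2)
    det <- sw * swxx - swx^2
    if (det <= .Machine$double.eps * sw * swxx + 1e-300)
      return(sum(w * y) / sw)
    (swxx * sum(w * y) - swx * sum(w * xc * y)) / det
  }, 0)
}

#' Fit a score-vs-age trajectory with a bootstrap band
#'
#' Local-linear smooth (Gaussian kernel, bandwidth half the age range by
#' default) of per-cell scores against donor age within one region, with a
#' simultaneous 95% bootstrap band (sup-t construction over resampled
#' curves, cells resampled with replacement stratified by donor).
#'
#' @param scores named per-cell scores (names = barcodes), e.g. from
#'   [compute_aging_score()].
#' @param meta per-cell metadata with `barcode`, `donor_id`, `age_years`,
#'   `region`.
#' @param region which region to fit (`"fovea"`/`"periphery"`); `NULL` fits
#'   all cells.
#' @param n_boot bootstrap replicates (default 500; the band's 2.5%/97.5%
#'   tail quantiles need several hundred replicates to be estimated stably).
#' @param seed integer seed.
#' @param grid_ages evaluation grid; default 25 points over the region's
#'   donor-age range.
#' @param bandwidth Gaussian kernel sd in years; default half the age range.
#' @return object of class `ScoreCurve`: list with `region`, `grid_ages`,
#'   `fitted`, `band_low`, `band_high`, `per_cell_scores`, `cell_meta`,
#'   `bandwidth`.
#' @export
fit_trajectory <- function(scores, meta, region = NULL, n_boot = 500L,
                           seed = 1L, grid_ages = NULL, bandwidth = NULL) {
  m <- meta[match(names(scores), meta$barcode), , drop = FALSE]
  keep <- if (is.null(region)) rep(TRUE, nrow(m)) else m$region == region
  m <- m[keep, , drop = FALSE]
  y <- unname(scores[keep])
  x <- m$age_years
  if (length(unique(x)) < 3L)
    stop("need at least 3 distinct donor ages in region ",
         if (is.null(region)) "all" else region)
  if (is.null(bandwidth)) bandwidth <- 0.5 * diff(range(x))
  if (is.null(grid_ages)) grid_ages <- seq(min(x), max(x), length.out = 25L)
  grid_ages <- sort(grid_ages)
  fitted <- loclin_fit(x, y, grid_ages, bandwidth)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  donor_idx <- split(seq_along(x), m$donor_id)
  boot <- matrix(NA_real_, n_boot, length(grid_ages))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(donor_idx, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]), use.names = FALSE)
    boot[b, ] <- loclin_fit(x[idx], y[idx], grid_ages, bandwidth)
  }
  # sup-t simultaneous 95% band: fitted +/- c * sd(g), with c the 95%
  # quantile of the bootstrap sup of |curve - fitted| / sd over the grid;
  # covers the whole curve, not just each grid point marginally
  sds <- apply(boot, 2L, stats::sd)
  scl <- ifelse(sds > 0, sds, 1)
  sup_dev <- apply(abs(sweep(boot, 2L, fitted)) /
                     rep(scl, each = n_boot), 1L, max)
  crit <- stats::quantile(sup_dev, 0.95, na.rm = TRUE, names = FALSE)
  structure(list(region = if (is.null(region)) "all" else region,
                 grid_ages = grid_ages, fitted = fitted,
                 band_low = fitted - crit * sds,
                 band_high = fitted + crit * sds,
                 per_cell_scores = stats::setNames(y, m$barcode),
                 cell_meta = m, bandwidth = bandwidth),
            class = "ScoreCurve")
}

#' @export
print.ScoreCurve <- function(x, ...) {
  cat(sprintf("ScoreCurve (%s): %d cells, ages %.3g-%.3g, bandwidth %.3g\n",
              x$region, length(x$per_cell_scores),
              min(x$grid_ages), max(x$grid_ages), x$bandwidth))
  invisible(x)
}

#' Test the fovea-periphery trajectory gradient
#'
#' `delta` is the mean of (foveal fitted - peripheral fitted) over the shared
#' age grid; the null distribution comes from permuting region labels among
#' cells within each donor and refitting both curves. The two-sided p-value
#' uses |delta| with the standard (1 + x)/(n + 1) correction.
#'
#' @param curve_fovea,curve_periphery [fit_trajectory()] results on a shared
#'   `grid_ages`.
#' @param n_perm permutations (default 200).
#' @param seed integer seed.
#' @return list with `delta` and `p`.
#' @export
region_gradient_test <- function(curve_fovea, curve_periphery,
                                 n_perm = 200L, seed = 1L) {
  if (!isTRUE(all.equal(curve_fovea$grid_ages, curve_periphery$grid_ages)))
    stop("curves must share an age grid")
  grid <- curve_fovea$grid_ages
  bw <- curve_fovea$bandwidth
  y <- c(curve_fovea$per_cell_scores, curve_periphery$per_cell_scores)
  x <- c(curve_fovea$cell_meta$age_years, curve_periphery$cell_meta$age_years)
  donor <- c(curve_fovea$cell_meta$donor_id, curve_periphery$cell_meta$donor_id)
  is_fov <- rep(c(TRUE, FALSE), c(length(curve_fovea$per_cell_scores),
                                  length(curve_periphery$per_cell_scores)))
  delta_for <- function(fov) {
    mean(loclin_fit(x[fov], y[fov], grid, bw) -
           loclin_fit(x[!fov], y[!fov], grid, bw))
  }
  delta <- delta_for(is_fov)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  donor_idx <- split(seq_along(x), donor)
  null <- vapply(seq_len(n_perm), function(b) {
    fov <- is_fov
    for (ii in donor_idx) fov[ii] <- fov[ii][sample.int(length(ii))]
    delta_for(fov)
  }, 0)
  p <- (1 + sum(abs(null) >= abs(delta))) / (n_perm + 1)
  list(delta = delta, p = p)
}

#' Single-gene expression trajectory
#'
#' The trajectory smoother of [fit_trajectory()] applied to one gene's
#' normalized expression (no \[0, 1\] rescale).
#'
#' @param norm a [normalize_counts()] result.
#' @param gene gene symbol.
#' @inheritParams fit_trajectory
#' @return a `ScoreCurve` on the expression scale.
#' @export
gene_trajectory <- function(norm, gene, region = NULL, n_boot = 500L,
                            seed = 1L, grid_ages = NULL, bandwidth = NULL) {
  if (!gene %in% norm$gene_ids) stop("gene absent: ", gene)
  expr <- stats::setNames(as.vector(norm$values[gene, , drop = FALSE]),
                          norm$cell_ids)
  fit_trajectory(expr, norm$meta, region = region, n_boot = n_boot,
                 seed = seed, grid_ages = grid_ages, bandwidth = bandwidth)
}

#' Stage-wise drift of a gene signature within a cell type
#'
#' Mean z-scored expression (z across the cell type's cells) of a gene list
#' in one annotated cell type, per age stage. Z-scoring makes the result
#' invariant to per-gene affine rescaling.
#'
#' @param norm a [normalize_counts()] result.
#' @param annot a `CellAnnotation`.
#' @param gene_list nonempty character vector of genes.
#' @param cell_type annotated type to profile.
#' @param stages per-cell stage labels (defaults to staging donor ages).
#' @param stage_map ordered stage definitions.
#' @return named numeric vector, one mean signature value per stage
#'   (NA where the cell type is absent).
#' @export
signature_drift <- function(norm, annot, gene_list, cell_type,
                            stages = NULL, stage_map = default_stage_map()) {
  if (!length(gene_list)) stop("empty gene list")
  absent <- setdiff(gene_list, norm$gene_ids)
  if (length(absent)) stop("gene(s) absent: ", paste(absent, collapse = ", "))
  if (is.null(stages))
    stages <- vapply(norm$meta$age_years, assign_stage, "", stage_map = stage_map)
  ann <- annot$cells[match(norm$cell_ids, annot$cells$barcode), ]
  in_type <- which(ann$cell_type == cell_type)
  if (!length(in_type)) stop("no cells of type ", cell_type)
  x <- as.matrix(norm$values[gene_list, in_type, drop = FALSE])
  z <- t(scale(t(x)))
  z[is.na(z)] <- 0
  sig <- colMeans(z)
  st <- stages[in_type]
  vapply(stage_map$stage_name, function(s) {
    ii <- which(st == s)
    if (!length(ii)) NA_real_ else mean(sig[ii])
  }, 0)
}
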