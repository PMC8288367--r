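#' Construct a CellMatrix
#'
#' The universal input container of the pipeline: a sparse gene x cell matrix
#' of raw counts together with aligned per-cell metadata (donor, species,
#' age in years, retinal region) and, optionally, ground-truth labels carried
#' over from the synthetic-data generator.
#'
#' @param counts non-negative integer matrix (genes x cells); coerced to
#'   [Matrix::dgCMatrix-class]. Rownames are gene symbols, colnames barcodes.
#' @param meta data.frame with one row per cell and columns `barcode`,
#'   `donor_id`, `species` (`human`/`macaque`), `age_years` (non-negative
#'   real; an 8-day infant encodes as 0.02), `region` (`fovea`/`periphery`).
#' @param truth optional data.frame of per-cell ground-truth labels
#'   (`barcode`, `cell_type`, `subtype`), kept for recovery testing.
#' @return object of class `CellMatrix`: list with `counts`, `gene_ids`,
#'   `cell_ids`, `meta`, `truth`.
#' @export
cell_matrix <- function(counts, meta, truth = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  obj <- structure(
    list(counts = counts,
         gene_ids = rownames(counts),
         cell_ids = colnames(counts),
         meta = as.data.frame(meta),
         truth = if (is.null(truth)) NULL else as.data.frame(truth)),
    class = "CellMatrix")
  validate_cell_matrix(obj)
  obj
}

REGIONS <- c("fovea", "periphery")
SPECIES <- c("human", "macaque")

#' Validate a CellMatrix
#'
#' Checks the container invariants: integral non-negative counts, unique
#' gene/cell identifiers, exactly one metadata record per cell, and the
#' region/species enumerations.
#'
#' @param x a `CellMatrix`.
#' @return `x`, invisibly; stops with an informative error otherwise.
#' @export
validate_cell_matrix <- function(x) {
  stopifnot(inherits(x, "CellMatrix"))
  cts <- x$counts
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    stop("counts must carry gene rownames and barcode colnames")
  if (anyDuplicated(rownames(cts))) stop("gene_ids must be unique")
  if (anyDuplicated(colnames(cts))) stop("cell_ids must be unique")
  if (length(cts@x) && (any(cts@x < 0) || any(cts@x != round(cts@x))))
    stop("counts must be non-negative integers")
  m <- x$meta
  need <- c("barcode", "donor_id", "species", "age_years", "region")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (nrow(m) != ncol(cts)) stop("metadata must have exactly one record per cell")
  unmatched <- setdiff(colnames(cts), m$barcode)
  if (length(unmatched))
    stop("metadata missing barcode(s): ", paste(utils::head(unmatched, 5), collapse = ", "))
  if (anyDuplicated(m$barcode)) stop("duplicated barcodes in metadata")
  if (!all(m$region %in% REGIONS))
    stop("region must be one of: ", paste(REGIONS, collapse = ", "))
  if (!all(m$species %in% SPECIES))
    stop("species must be one of: ", paste(SPECIES, collapse = ", "))
  if (any(m$age_years < 0)) stop("age_years must be non-negative")
  invisible(x)
}

#' @export
print.CellMatrix <- function(x, ...) {
  cat(sprintf("CellMatrix: %d genes x %d cells (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$meta$species), collapse = "+")))
  cat(sprintf("  donors: %s\n", paste(unique(x$meta$donor_id), collapse = ", ")))
  cat(sprintf("  regions: %s\n",
              paste(names(table(x$meta$region)), table(x$meta$region),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Read a CellMatrix from a 10x-style directory
#'
#' Expects the CellRanger v3 triplet `matrix.mtx`, `features.tsv`,
#' `barcodes.tsv` plus a `cells.tsv` metadata table (tab-separated, header
#' `barcode donor_id species age_years region`). Metadata rows are joined to
#' matrix barcodes by exact match. A `truth.tsv` written by the generator is
#' picked up when present.
#'
#' @param dir_path directory containing the files above.
#' @return a validated [cell_matrix()].
#' @export
read_matrix <- function(dir_path) {
  need <- c("matrix.mtx", "features.tsv", "barcodes.tsv", "cells.tsv")
  paths <- file.path(dir_path, need)
  absent <- need[!file.exists(paths)]
  if (length(absent))
    stop("missing file(s) in ", dir_path, ": ", paste(absent, collapse = ", "))
  mm <- Matrix::readMM(paths[1])
  if (length(mm@x) && any(mm@x != round(mm@x)))
    stop("matrix.mtx contains non-integer counts")
  features <- utils::read.delim(paths[2], header = FALSE, stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(paths[3], header = FALSE, stringsAsFactors = FALSE)
  rownames(mm) <- features[[1]]
  colnames(mm) <- barcodes[[1]]
  meta <- utils::read.delim(paths[4], header = TRUE, stringsAsFactors = FALSE)
  unmatched <- setdiff(colnames(mm), meta$barcode)
  if (length(unmatched))
    stop("cells.tsv missing barcode(s): ", paste(utils::head(unmatched, 5), collapse = ", "))
  meta <- meta[match(colnames(mm), meta$barcode), , drop = FALSE]
  rownames(meta) <- NULL
  truth_path <- file.path(dir_path, "truth.tsv")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- utils::read.delim(truth_path, header = TRUE, stringsAsFactors = FALSE)
    truth <- truth[match(colnames(mm), truth$barcode), , drop = FALSE]
    rownames(truth) <- NULL
  }
  cell_matrix(mm, meta, truth = truth)
}

#' Write a CellMatrix to a 10x-style directory
#'
#' Emits `matrix.mtx` in Matrix Market coordinate **integer** format plus
#' `features.tsv`, `barcodes.tsv`, `cells.tsv` (and `truth.tsv` when ground
#' truth is attached) such that [read_matrix()] round-trips exactly.
#'
#' @param x a `CellMatrix`; must have at least one cell.
#' @param dir_path output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_matrix <- function(x, dir_path) {
  validate_cell_matrix(x)
  if (ncol(x$counts) == 0L) stop("refusing to write a CellMatrix with 0 cells")
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir_path)) stop("cannot create directory ", dir_path)
  tm <- methods::as(x$counts, "TsparseMatrix")
  con <- file(file.path(dir_path, "matrix.mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(tm), ncol(tm), length(tm@x))), con)
  if (length(tm@x))
    writeLines(sprintf("%d %d %d", tm@i + 1L, tm@j + 1L, as.integer(tm@x)), con)
  close(con)
  writeLines(x$gene_ids, file.path(dir_path, "features.tsv"))
  writeLines(x$cell_ids, file.path(dir_path, "barcodes.tsv"))
  utils::write.table(x$meta, file.path(dir_path, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$truth))
    utils::write.table(x$truth, file.path(dir_path, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir_path)
}
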