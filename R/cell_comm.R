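#' Read a ligand-receptor pair table
#'
#' Tab-separated with header; columns `ligand` and `receptor` (a `pair_id`
#' column is honored, otherwise `ligand_receptor` ids are built).
#'
#' @param path TSV file.
#' @return data.frame (`LRDatabase`) with `ligand`, `receptor`, `pair_id`.
#' @export
read_lr_pairs <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  lr_database(tab$ligand, tab$receptor,
              pair_id = if ("pair_id" %in% names(tab)) tab$pair_id else NULL)
}

#' Construct a ligand-receptor database
#'
#' @param ligand,receptor gene symbol vectors of equal length.
#' @param pair_id optional unique ids; default `ligand_receptor`.
#' @return data.frame with class `LRDatabase`.
#' @export
lr_database <- function(ligand, receptor, pair_id = NULL) {
  if (!length(ligand)) stop("empty LR database")
  if (any(!nzchar(ligand)) || any(!nzchar(receptor)))
    stop("empty gene symbol in LR database")
  if (is.null(pair_id)) pair_id <- paste(ligand, receptor, sep = "_")
  if (anyDuplicated(pair_id)) stop("pair_ids must be unique")
  structure(data.frame(ligand = ligand, receptor = receptor,
                       pair_id = pair_id, stringsAsFactors = FALSE),
            class = c("LRDatabase", "data.frame"))
}

#' Scaled differential-expression magnitude per gene within a cell type
#'
#' |log2 fold change| of each gene between two age stages within one
#' annotated cell type (pseudocount 1 on de-logged means), z-scaled across
#' the genes of that cell type. Library-depth changes cancel through the
#' normalization, so magnitudes are invariant to uniform depth rescaling.
#'
#' @param norm a [normalize_counts()] result.
#' @param annot a `CellAnnotation`.
#' @param cell_type annotated type to contrast.
#' @param contrast two stage names, `c(numerator, baseline)`; default
#'   `c("aging", "adult")`.
#' @param stages per-cell stage labels (defaults to staging donor ages).
#' @param signed keep the sign of the fold change instead of |.| (default
#'   FALSE, matching a magnitude reading).
#' @param stage_map ordered stage definitions.
#' @return named numeric vector of scaled magnitudes, one per gene.
#' @export
de_magnitude <- function(norm, annot, cell_type, contrast = c("aging", "adult"),
                         stages = NULL, signed = FALSE,
                         stage_map = default_stage_map()) {
  if (is.null(stages))
    stages <- vapply(norm$meta$age_years, assign_stage, "", stage_map = stage_map)
  ann <- annot$cells[match(norm$cell_ids, annot$cells$barcode), ]
  idx_num <- which(ann$cell_type == cell_type & stages == contrast[1L])
  idx_base <- which(ann$cell_type == cell_type & stages == contrast[2L])
  if (!length(idx_num) || !length(idx_base))
    stop("cell type ", cell_type, " missing in a contrast stage")
  lfc <- log2((linear_mean(norm$values, idx_num) + 1) /
                (linear_mean(norm$values, idx_base) + 1))
  mag <- if (signed) lfc else abs(lfc)
  s <- stats::sd(mag)
  z <- if (is.na(s) || s == 0) rep(0, length(mag)) else (mag - mean(mag)) / s
  stats::setNames(z, norm$gene_ids)
}

#' Per-gene detection fraction by cell type
#'
#' @param norm a [normalize_counts()] result.
#' @param annot a `CellAnnotation`.
#' @return matrix genes x cell types of detection fractions.
#' @export
detection_fraction <- function(norm, annot) {
  ann <- annot$cells[match(norm$cell_ids, annot$cells$barcode), ]
  types <- sort(unique(ann$cell_type))
  out <- vapply(types, function(ct)
    frac_detected(norm$values, which(ann$cell_type == ct)),
    numeric(nrow(norm$values)))
  rownames(out) <- norm$gene_ids
  out
}

#' Build the ligand-receptor differential communication graph
#'
#' For every LR pair and every (sender, receiver) cell-type combination with
#' the ligand detected in at least `expr_filter` of sender cells and the
#' receptor in at least `expr_filter` of receiver cells, an edge connects
#' the (ligand, sender) node to the (receptor, receiver) node with score
#' equal to the sum of the two nodes' scaled differential-expression
#' magnitudes.
#'
#' @param lr_db an [lr_database()].
#' @param magnitudes named list: cell type -> named magnitude vector from
#'   [de_magnitude()]. Its names define the sender/receiver universe.
#' @param detect_frac genes x cell types detection matrix from
#'   [detection_fraction()].
#' @param expr_filter detection gate, default 0.10.
#' @return object of class `CommGraph`: list with `nodes` (data.frame
#'   `node_id`, `gene`, `cell_type`, `role`, `de_magnitude`), `edges`
#'   (data.frame `ligand_node`, `receptor_node`, `pair_id`, `sender`,
#'   `receiver`, `score`) and `k_filter` (NA until [top_k_edges()]).
#' @export
build_network <- function(lr_db, magnitudes, detect_frac, expr_filter = 0.10) {
  stopifnot(inherits(lr_db, "LRDatabase"))
  if (!nrow(lr_db)) stop("empty LR database")
  types <- names(magnitudes)
  if (is.null(types) || !length(types)) stop("magnitudes must be a named list")
  edges <- list()
  for (k in seq_len(nrow(lr_db))) {
    lig <- lr_db$ligand[k]; rec <- lr_db$receptor[k]
    for (s in types) {
      if (!lig %in% names(magnitudes[[s]])) next
      if (!lig %in% rownames(detect_frac) ||
          detect_frac[lig, s] < expr_filter) next
      for (r in types) {
        if (!rec %in% names(magnitudes[[r]])) next
        if (!rec %in% rownames(detect_frac) ||
            detect_frac[rec, r] < expr_filter) next
        edges[[length(edges) + 1L]] <- data.frame(
          ligand_node = paste(lig, s, sep = "@"),
          receptor_node = paste(rec, r, sep = "@"),
          pair_id = lr_db$pair_id[k], sender = s, receiver = r,
          score = unname(magnitudes[[s]][lig] + magnitudes[[r]][rec]),
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(ligand_node = character(0), receptor_node = character(0),
               pair_id = character(0), sender = character(0),
               receiver = character(0), score = numeric(0))
  graph <- structure(list(nodes = NULL, edges = edges, k_filter = NA_integer_),
                     class = "CommGraph")
  rebuild_nodes(graph, magnitudes)
}

# Derive the node table from the surviving edges.
rebuild_nodes <- function(graph, magnitudes = NULL) {
  e <- graph$edges
  split_node <- function(id) do.call(rbind, strsplit(id, "@", fixed = TRUE))
  nodes <- unique(rbind(
    if (nrow(e)) data.frame(node_id = e$ligand_node,
                            gene = split_node(e$ligand_node)[, 1L],
                            cell_type = e$sender, role = "ligand",
                            stringsAsFactors = FALSE),
    if (nrow(e)) data.frame(node_id = e$receptor_node,
                            gene = split_node(e$receptor_node)[, 1L],
                            cell_type = e$receiver, role = "receptor",
                            stringsAsFactors = FALSE)))
  if (is.null(nodes))
    nodes <- data.frame(node_id = character(0), gene = character(0),
                        cell_type = character(0), role = character(0))
  nodes$de_magnitude <- if (is.null(magnitudes)) NA_real_ else
    mapply(function(g, ct) unname(magnitudes[[ct]][g]), nodes$gene, nodes$cell_type)
  graph$nodes <- nodes
  graph
}

#' @export
print.CommGraph <- function(x, ...) {
  cat(sprintf("CommGraph: %d nodes, %d edges%s\n",
              nrow(x$nodes), nrow(x$edges),
              if (is.na(x$k_filter)) "" else sprintf(" (top %d)", x$k_filter)))
  invisible(x)
}

#' Keep the k highest-scoring edges
#'
#' Edges are ranked by score (descending) with deterministic tie-breaking by
#' `pair_id`, then sender, then receiver (lexicographic); nodes left without
#' an edge are dropped. `k` larger than the edge count retains everything.
#'
#' @param graph a [build_network()] result.
#' @param k number of edges to keep (default 100).
#' @return the filtered `CommGraph` with `k_filter = k`.
#' @export
top_k_edges <- function(graph, k = 100L) {
  stopifnot(inherits(graph, "CommGraph"))
  if (k < 1L) stop("k must be at least 1")
  e <- graph$edges
  o <- order(-e$score, e$pair_id, e$sender, e$receiver)
  e <- e[utils::head(o, k), , drop = FALSE]
  rownames(e) <- NULL
  mags <- stats::setNames(graph$nodes$de_magnitude, graph$nodes$node_id)
  graph$edges <- e
  graph$k_filter <- as.integer(k)
  graph <- rebuild_nodes(graph)
  graph$nodes$de_magnitude <- unname(mags[graph$nodes$node_id])
  graph
}

#' Export a communication graph's edge list
#'
#' @param graph a `CommGraph`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_comm_edges <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
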