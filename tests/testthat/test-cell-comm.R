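# Hand-set magnitudes / detection tables for arithmetic-level checks.
hand_graph <- function(mags, det = NULL, expr_filter = 0.10, db = NULL) {
  genes <- unique(unlist(lapply(mags, names)))
  if (is.null(det))
    det <- matrix(1, length(genes), length(mags),
                  dimnames = list(genes, names(mags)))
  if (is.null(db)) db <- lr_database("L", "R")
  build_network(db, mags, det, expr_filter = expr_filter)
}

test_that("edge scores are the sum of the two node magnitudes", {
  mags <- list(S = c(L = 1.2, R = -0.3), T = c(L = 0.1, R = 0.8))
  g <- hand_graph(mags)
  e <- g$edges
  hit <- e[e$sender == "S" & e$receiver == "T", ]
  expect_equal(hit$score, 1.2 + 0.8)
  # all magnitudes zero -> all edge scores zero
  zero <- hand_graph(list(S = c(L = 0, R = 0), T = c(L = 0, R = 0)))
  expect_true(all(zero$edges$score == 0))
  expect_error(build_network(structure(data.frame(), class = c("LRDatabase", "data.frame")),
                             mags, matrix(1)), "empty")
})

test_that("the expression filter removes undetected ligands/receptors", {
  mags <- list(S = c(L = 1, R = 1), T = c(L = 1, R = 1))
  det <- matrix(c(0.05, 1, 1, 1), 2, 2,
                dimnames = list(c("L", "R"), c("S", "T")))
  g <- hand_graph(mags, det)
  expect_false(any(g$edges$sender == "S"))  # ligand below filter in S
  expect_true(any(g$edges$sender == "T"))
})

test_that("top_k keeps exactly k edges with deterministic tie-breaking", {
  set.seed(8)
  n_lig <- 15
  db <- lr_database(sprintf("L%02d", 1:n_lig), sprintf("R%02d", 1:n_lig))
  genes <- c(db$ligand, db$receptor)
  mags <- list(A = setNames(rnorm(2 * n_lig), genes),
               B = setNames(rnorm(2 * n_lig), genes),
               C = setNames(rnorm(2 * n_lig), genes))
  det <- matrix(1, length(genes), 3, dimnames = list(genes, c("A", "B", "C")))
  g <- build_network(db, mags, det)
  expect_equal(nrow(g$edges), n_lig * 9)  # 135 candidates
  top <- top_k_edges(g, 100)
  expect_equal(nrow(top$edges), 100)
  expect_true(all(top$nodes$node_id %in%
                    c(top$edges$ligand_node, top$edges$receptor_node)))
  # saturation: k beyond the candidate count keeps everything
  expect_equal(nrow(top_k_edges(g, 1000)$edges), n_lig * 9)
  # ties at the cut resolve lexicographically and reproducibly
  tie_mags <- list(A = c(L1 = 0.5, L2 = 0.5, R1 = 0.5, R2 = 0.5))
  tie_db <- lr_database(c("L1", "L2"), c("R1", "R2"))
  tie_det <- matrix(1, 4, 1, dimnames = list(c("L1", "L2", "R1", "R2"), "A"))
  tg <- build_network(tie_db, tie_mags, tie_det)
  expect_equal(top_k_edges(tg, 1)$edges$pair_id, "L1_R1")
  expect_identical(top_k_edges(tg, 1)$edges, top_k_edges(tg, 1)$edges)
})

test_that("retained edges are invariant to input edge order", {
  set.seed(9)
  db <- lr_database(sprintf("L%02d", 1:10), sprintf("R%02d", 1:10))
  genes <- c(db$ligand, db$receptor)
  mags <- list(A = setNames(rnorm(20), genes), B = setNames(rnorm(20), genes))
  det <- matrix(1, 20, 2, dimnames = list(genes, c("A", "B")))
  g1 <- top_k_edges(build_network(db, mags, det), 10)
  db2 <- db[sample(nrow(db)), ]
  class(db2) <- class(db)
  g2 <- top_k_edges(build_network(db2, mags, det), 10)
  key <- function(e) sort(paste(e$pair_id, e$sender, e$receiver))
  expect_identical(key(g1$edges), key(g2$edges))
})

test_that("de_magnitude ranks a planted aged shift first in its cell type", {
  # no global trend genes here: the contrast isolates the LR aging signal
  cfg <- small_config(seed = 120, n_genes = 400,
                      planted_trends = list(n_up = 0, n_down = 0,
                                            per_stage_log_fold = 1.0))
  # enough MG cells per stage that null fold-change noise stays small
  cfg$cell_types$MG$n_fovea <- 300L
  cfg$cell_types$MG$n_periphery <- 300L
  sim0 <- simulate_retina(cfg)
  norm0 <- normalize_counts(sim0$matrix)
  mag_mg <- de_magnitude(norm0, annotation_from_truth(sim0$matrix), "MG")
  # VEGFA and BDNF are shifted in aged MG senders under the default config
  expect_true(all(c("VEGFA", "BDNF") %in%
                    names(sort(mag_mg, decreasing = TRUE)[1:4])))
  sim <- small_sim()
  norm <- small_norm()
  ann <- annotation_from_truth(sim$matrix)
  # identical stage populations -> all magnitudes zero
  m <- sim$matrix
  adult <- m$meta$age_years < 40
  m2 <- cell_matrix(m$counts[, adult], m$meta[adult, ], truth = m$truth[adult, ])
  # duplicate the adult cells as fake "aging" donors
  m3 <- m2; m3$meta$age_years <- 86
  m3$meta$barcode <- paste0(m3$meta$barcode, "x")
  m3$cell_ids <- m3$meta$barcode
  colnames(m3$counts) <- m3$meta$barcode
  m3$truth$barcode <- m3$meta$barcode
  comb <- cell_matrix(cbind(m2$counts, m3$counts), rbind(m2$meta, m3$meta),
                      truth = rbind(m2$truth, m3$truth))
  mags <- de_magnitude(normalize_counts(comb), annotation_from_truth(comb), "MG")
  expect_true(all(mags == 0))
  expect_error(de_magnitude(norm, ann, "MG", contrast = c("aging", "unstaged")),
               "missing")
})

test_that("planted LR pairs rank at the top among decoys end-to-end", {
  sim <- human_sim()
  norm <- human_norm()
  ann <- annotation_from_truth(sim$matrix)
  types <- unique(sim$truth$lr_signals$sender) |>
    union(unique(sim$truth$lr_signals$receiver)) |> union("cone")
  mags <- lapply(setNames(types, types), function(ct)
    de_magnitude(norm, ann, ct))
  det <- detection_fraction(norm, ann)
  db <- read_lr_pairs(system.file("extdata", "lr_pairs.tsv",
                                  package = "retinaAging"))
  g <- build_network(db, mags, det[, types, drop = FALSE])
  planted <- sim$truth$lr_signals
  planted_ids <- paste(planted$ligand, planted$receptor, sep = "_")
  n_planted <- nrow(planted)
  top <- top_k_edges(g, n_planted + 2)
  found <- mapply(function(pid, s, r)
    any(top$edges$pair_id == pid & top$edges$sender == s & top$edges$receiver == r),
    planted_ids, planted$sender, planted$receiver)
  expect_gte(mean(found), 0.9)
})
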