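test_that("clustering separates well-separated synthetic types", {
  cfg <- small_config(seed = 31, n_genes = 200)
  cfg$cell_types <- cfg$cell_types[c("rod", "MG")]
  cfg$cell_types$rod$n_fovea <- 150L; cfg$cell_types$rod$n_periphery <- 150L
  cfg$cell_types$MG$n_fovea <- 150L; cfg$cell_types$MG$n_periphery <- 150L
  cfg$rod_subtype_mix <- NULL; cfg$hc_mix <- NULL; cfg$lr_signals <- NULL
  cfg$planted_trends <- list(n_up = 0L, n_down = 0L, per_stage_log_fold = 1.0)
  sim <- simulate_retina(cfg)
  norm <- normalize_counts(sim$matrix)
  cl <- cluster_cells(norm, resolution = 0.2, seed = 99)
  truth <- sim$truth$cells$cell_type[match(norm$cell_ids, sim$truth$cells$barcode)]
  expect_gte(mclust::adjustedRandIndex(cl, truth), 0.9)
  # determinism under a fixed seed
  expect_identical(cl, cluster_cells(norm, resolution = 0.2, seed = 99))
})

test_that("duplicated identical cells collapse to one cluster", {
  cts <- Matrix::Matrix(rep(c(5, 0, 2, 7), 60), nrow = 4, sparse = TRUE)
  m <- toy_matrix(cts)
  expect_error(cluster_cells(normalize_counts(m)), "degenerate|identical")
  expect_error(cluster_cells(normalize_counts(toy_matrix(cts[, 1:10]))),
               "at least 50")
})

test_that("marker scoring labels clusters correctly on a 6-type mixture", {
  sim <- small_sim()
  norm <- small_norm()
  truth <- sim$truth$cells
  # score against true partitions: isolates the scoring stage
  clusters <- as.integer(factor(truth$cell_type))[match(norm$cell_ids, truth$barcode)]
  ann <- score_cell_types(norm, clusters, default_marker_panel())
  acc <- mean(ann$cells$cell_type ==
                truth$cell_type[match(ann$cells$barcode, truth$barcode)])
  expect_gte(acc, 0.95)
  expect_false(any(ann$cells$tie_flag))
})

test_that("a cluster expressing only one type's markers gets that label", {
  panel <- marker_panel(entries = list(rod = c("NRL", "RHO"), MG = c("RLBP1")))
  cts <- Matrix::Matrix(0, nrow = 3, ncol = 60, sparse = TRUE,
                        dimnames = list(c("NRL", "RHO", "RLBP1"), NULL))
  cts[1:2, 1:30] <- 8; cts[3, 31:60] <- 8; cts[3, 1:30] <- 1  # keep libsizes > 0
  ann <- score_cell_types(normalize_counts(toy_matrix(cts)),
                          rep(1:2, each = 30), panel)
  expect_equal(unique(ann$cells$cell_type[1:30]), "rod")
  expect_equal(unique(ann$cells$cell_type[31:60]), "MG")
})

test_that("tied type scores break lexicographically with a flag", {
  panel <- marker_panel(entries = list(alpha = "g1", beta = "g2"))
  cts <- Matrix::Matrix(rbind(rep(c(4, 1), each = 20),
                              rep(c(1, 4), each = 20)), sparse = TRUE)
  rownames(cts) <- c("g1", "g2")
  # two clusters, mirror-image markers: per-cluster scores are symmetric, so
  # scoring a single cluster containing everything ties alpha vs beta
  ann <- score_cell_types(normalize_counts(toy_matrix(cts)),
                          rep(1, 40), panel)
  expect_true(all(ann$cells$cell_type == "alpha"))
  expect_true(all(ann$cells$tie_flag))
})

test_that("rod subtype rule is a detection threshold and ignores non-rods", {
  norm <- small_norm()
  ann <- classify_rod_subtype(norm, annotation_from_truth(small_sim()$matrix))
  cells <- ann$cells
  rods <- cells$cell_type == "rod"
  idx <- match(cells$barcode[rods], norm$cell_ids)
  detected <- as.vector(norm$values["MYO9A", idx]) > 0
  expect_identical(cells$subtype[rods], ifelse(detected, "MYO9A+", "MYO9A-"))
  expect_true(all(is.na(cells$subtype[cells$cell_type == "MG"])))
  expect_error(classify_rod_subtype(norm, ann, gene = "NOPE"), "absent")
})

test_that("injected MYO9A dropout moves misclassification by the same amount", {
  sim <- small_sim()
  truth <- sim$truth$cells
  m <- sim$matrix
  pos <- truth$barcode[!is.na(truth$subtype) & truth$subtype == "MYO9A+"]
  set.seed(77)
  corrupt <- sample(pos, round(0.3 * length(pos)))
  cts <- m$counts
  cts["MYO9A", corrupt] <- 0
  norm <- normalize_counts(cell_matrix(Matrix::drop0(cts), m$meta, truth = m$truth))
  ann <- classify_rod_subtype(norm, annotation_from_truth(m))
  called <- ann$cells$subtype[match(pos, ann$cells$barcode)]
  miss <- mean(called == "MYO9A-")
  expect_equal(miss, 0.3, tolerance = 0.02)
})

test_that("HC subtype scoring recovers planted H1/H2 labels", {
  sim <- small_sim()
  norm <- small_norm()
  ann <- classify_hc_subtype(norm, annotation_from_truth(sim$matrix))
  truth <- sim$truth$cells
  hc <- ann$cells$cell_type == "HC"
  acc <- mean(ann$cells$subtype[hc] ==
                truth$subtype[match(ann$cells$barcode[hc], truth$barcode)])
  expect_gte(acc, 0.98)
})

test_that("HC cells expressing only H1 markers are H1; ties go to H1", {
  genes <- c("LHX1", "PCP4", "ISL1", "CALB1")
  cts <- Matrix::Matrix(1, nrow = 4, ncol = 20, sparse = TRUE,
                        dimnames = list(genes, NULL))
  cts[1:2, 1:10] <- 9   # H1 markers high in the first half
  cts[3:4, 11:20] <- 9  # H2 markers high in the second half
  m <- toy_matrix(cts)
  hc_truth <- function(mm) data.frame(barcode = mm$cell_ids, cell_type = "HC",
                                      subtype = NA, stage = "adult")
  ann <- annotation_from_truth(cell_matrix(m$counts, m$meta, truth = hc_truth(m)))
  out <- classify_hc_subtype(normalize_counts(m), ann)
  expect_true(all(out$cells$subtype[1:10] == "H1"))
  expect_true(all(out$cells$subtype[11:20] == "H2"))
  expect_false(any(out$cells$tie_flag))
  # all rule genes flat: scores tie at zero, lexicographic pick H1, flagged
  flat <- Matrix::Matrix(1, nrow = 4, ncol = 10, sparse = TRUE,
                         dimnames = list(genes, NULL))
  mf <- toy_matrix(flat)
  annf <- annotation_from_truth(cell_matrix(mf$counts, mf$meta, truth = hc_truth(mf)))
  outf <- classify_hc_subtype(normalize_counts(mf), annf)
  expect_true(all(outf$cells$subtype == "H1"))
  expect_true(all(outf$cells$tie_flag))
})

test_that("proportion estimates sum to one with CIs containing the point", {
  sim <- small_sim()
  ann <- classify_hc_subtype(small_norm(), annotation_from_truth(sim$matrix))
  meta <- sim$matrix$meta
  meta$stage <- vapply(meta$age_years, assign_stage, "")
  tab <- estimate_proportions(ann, meta, c("region", "stage"),
                              label_col = "subtype", n_boot = 200, seed = 3)
  sums <- tapply(tab$proportion, tab$group, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(tab$ci_low <= tab$proportion & tab$proportion <= tab$ci_high))
  # single-label group: proportion 1 with degenerate CI
  one <- data.frame(barcode = sprintf("b%d", 1:30), donor_id = "d",
                    species = "human", age_years = 35, region = "fovea")
  ann1 <- structure(list(cells = data.frame(
    barcode = one$barcode, cluster_id = 1L, cell_type = "rod",
    subtype = NA_character_, tie_flag = FALSE), panel = default_marker_panel()),
    class = "CellAnnotation")
  t1 <- estimate_proportions(ann1, one, "region", n_boot = 200, seed = 1)
  expect_equal(t1$proportion, 1)
  expect_equal(t1$ci_low, 1); expect_equal(t1$ci_high, 1)
})

test_that("co-positivity query counts cells detected in every gene", {
  genes <- c("OTX2x", "RLBP1x")
  cts <- Matrix::Matrix(rbind(c(1, 1, 0, 2), c(1, 0, 1, 3)), sparse = TRUE,
                        dimnames = list(genes, NULL))
  m <- toy_matrix(cts)
  ann <- annotation_from_truth(cell_matrix(m$counts, m$meta, truth = data.frame(
    barcode = m$cell_ids, cell_type = "MG", subtype = NA, stage = "adult")))
  res <- co_positive(normalize_counts(m), ann, genes)
  expect_equal(res$fraction, 0.5)
  expect_setequal(res$barcodes, m$cell_ids[c(1, 4)])
})
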