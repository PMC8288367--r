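test_that("aging score is extremal, bounded and order-preserving", {
  up <- c("u1", "u2"); down <- c("d1", "d2")
  cts <- Matrix::Matrix(rbind(c(9, 5, 1), c(9, 5, 1),
                              c(1, 5, 9), c(1, 5, 9)), sparse = TRUE,
                        dimnames = list(c(up, down), NULL))
  norm <- normalize_counts(toy_matrix(cts), scale_total = 1)
  gs <- aging_gene_set(up, down)
  s <- compute_aging_score(norm, gs)
  expect_equal(unname(s[1]), 1)  # maximal in up, minimal in down
  expect_equal(unname(s[3]), 0)
  expect_true(all(s >= 0 & s <= 1))
  # permuting cells permutes scores identically
  perm <- c(2, 3, 1)
  m2 <- toy_matrix(cts[, perm])
  s2 <- compute_aging_score(normalize_counts(m2, scale_total = 1), gs)
  expect_equal(unname(s2), unname(s[perm]))
  expect_error(compute_aging_score(norm, aging_gene_set("absent1", "absent2")),
               "no gene-set genes")
  expect_error(aging_gene_set(c("a", "b"), c("b")), "disjoint")
})

test_that("score tracks donor age when trend genes rise with stage", {
  sim <- small_sim()
  norm <- small_norm()
  gs <- aging_gene_set(sim$truth$up_genes, sim$truth$down_genes)
  s <- compute_aging_score(norm, gs)
  rho <- cor(s, norm$meta$age_years, method = "spearman")
  expect_gte(rho, 0.8)
})

test_that("the packaged synthetic gene set loads and matches the generator", {
  path <- system.file("extdata", "aging_geneset_synthetic.tsv",
                      package = "retinaAging")
  gs <- read_aging_geneset(path)
  sim <- small_sim()
  expect_setequal(gs$up_genes, sim$truth$up_genes)
  expect_setequal(gs$down_genes, sim$truth$down_genes)
})

test_that("trajectory fitting is exact on flat input and seed-stable", {
  meta <- data.frame(barcode = sprintf("c%03d", 1:300),
                     donor_id = rep(c("a", "b", "c"), each = 100),
                     species = "human",
                     age_years = rep(c(35, 60, 85), each = 100),
                     region = "fovea")
  s <- setNames(rep(0.5, 300), meta$barcode)
  cv <- fit_trajectory(s, meta, "fovea", n_boot = 200, seed = 4)
  expect_equal(cv$fitted, rep(0.5, length(cv$grid_ages)))
  cv2 <- fit_trajectory(s, meta, "fovea", n_boot = 200, seed = 4)
  expect_identical(cv$band_low, cv2$band_low)
  expect_identical(cv$band_high, cv2$band_high)
  expect_error(fit_trajectory(s, meta[, ], "periphery"), "3 distinct")
})

test_that("a linear generating trend yields a monotone fit within its band", {
  set.seed(10)
  ages <- rep(c(30, 45, 60, 75, 90), each = 80)
  meta <- data.frame(barcode = sprintf("c%03d", seq_along(ages)),
                     donor_id = rep(sprintf("d%d", 1:5), each = 80),
                     species = "human", age_years = ages, region = "fovea")
  covered <- logical(50)
  positive_slope <- logical(50)
  for (r in 1:50) {
    y <- setNames(0.2 + 0.005 * ages + rnorm(length(ages), 0, 0.05),
                  meta$barcode)
    cv <- fit_trajectory(y, meta, "fovea", n_boot = 500, seed = r)
    truth_line <- 0.2 + 0.005 * cv$grid_ages
    covered[r] <- all(cv$band_low <= truth_line & truth_line <= cv$band_high)
    positive_slope[r] <- all(diff(cv$fitted) > 0)
  }
  expect_gte(mean(covered), 0.9)
  expect_true(all(positive_slope))
})

test_that("region gradient test detects a planted shift and respects symmetry", {
  set.seed(20)
  n <- 600
  donor <- rep(sprintf("d%d", 1:5), each = n / 5)
  ages <- rep(c(35, 50, 62, 80, 90), each = n / 5)
  region <- unlist(lapply(split(seq_len(n), donor), function(ii)
    sample(rep(c("fovea", "periphery"), length.out = length(ii)))),
    use.names = FALSE)
  meta <- data.frame(barcode = sprintf("c%04d", 1:n), donor_id = donor,
                     species = "human", age_years = ages, region = region)
  base <- 0.3 + 0.004 * ages + rnorm(n, 0, 0.05)
  y <- setNames(base + ifelse(region == "fovea", 0.1, 0), meta$barcode)
  grid <- seq(35, 90, length.out = 20)
  cf <- fit_trajectory(y, meta, "fovea", n_boot = 200, seed = 1, grid_ages = grid)
  cp <- fit_trajectory(y, meta, "periphery", n_boot = 200, seed = 2, grid_ages = grid)
  res <- region_gradient_test(cf, cp, n_perm = 200, seed = 3)
  expect_equal(res$delta, 0.1, tolerance = 0.02 / 0.1)  # +-0.02 absolute
  expect_lt(res$p, 0.05)
  # swapping the curves negates delta exactly
  swapped <- region_gradient_test(cp, cf, n_perm = 200, seed = 3)
  expect_equal(swapped$delta, -res$delta)
  # identical inputs: delta 0, p at the top of its range
  same <- region_gradient_test(cf, cf, n_perm = 200, seed = 4)
  expect_equal(same$delta, 0)
  expect_gte(same$p, 0.99)
})

test_that("gradient-test p-values are uniform under an exchangeable null", {
  set.seed(30)
  n <- 300
  donor <- rep(sprintf("d%d", 1:5), each = n / 5)
  ages <- rep(c(35, 50, 62, 80, 90), each = n / 5)
  grid <- seq(35, 90, length.out = 15)
  pvals <- vapply(1:60, function(r) {
    region <- unlist(lapply(split(seq_len(n), donor), function(ii)
      sample(rep(c("fovea", "periphery"), length.out = length(ii)))),
      use.names = FALSE)
    meta <- data.frame(barcode = sprintf("c%04d", 1:n), donor_id = donor,
                       species = "human", age_years = ages, region = region)
    y <- setNames(0.3 + 0.004 * ages + rnorm(n, 0, 0.05), meta$barcode)
    cf <- fit_trajectory(y, meta, "fovea", n_boot = 200, seed = 1, grid_ages = grid)
    cp <- fit_trajectory(y, meta, "periphery", n_boot = 200, seed = 1, grid_ages = grid)
    region_gradient_test(cf, cp, n_perm = 200, seed = r)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))  # discrete p grid ties
  expect_gt(ks$p.value, 0.01)
})

test_that("gene trajectories recover planted directions", {
  sim <- small_sim()
  norm <- small_norm()
  up_gene <- sim$truth$up_genes[1]
  dn_gene <- sim$truth$down_genes[1]
  cu <- gene_trajectory(norm, up_gene, region = "fovea", n_boot = 200, seed = 1)
  cd <- gene_trajectory(norm, dn_gene, region = "fovea", n_boot = 200, seed = 1)
  expect_gt(cor(cu$fitted, cu$grid_ages, method = "spearman"), 0)
  expect_lt(cor(cd$fitted, cd$grid_ages, method = "spearman"), 0)
  # all-zero gene: flat zero curve
  m <- sim$matrix
  cts <- m$counts; cts["G0500", ] <- 0
  nz <- normalize_counts(cell_matrix(Matrix::drop0(cts), m$meta))
  cz <- gene_trajectory(nz, "G0500", n_boot = 200, seed = 1)
  expect_equal(cz$fitted, rep(0, length(cz$grid_ages)))
  expect_error(gene_trajectory(norm, "NOPE"), "absent")
})

test_that("signature drift reflects planted monotone decline", {
  sim <- small_sim()
  norm <- small_norm()
  ann <- annotation_from_truth(sim$matrix)
  drift <- signature_drift(norm, ann, sim$truth$down_genes[1:10], "MG")
  expect_true(all(diff(drift) < 0))
  # z-scoring: invariant to per-gene affine rescaling of expression
  m <- sim$matrix
  norm2 <- norm
  g <- sim$truth$down_genes[1:10]
  norm2$values[g, ] <- norm2$values[g, ] * 3
  drift2 <- signature_drift(norm2, ann, g, "MG")
  expect_equal(drift2, drift, tolerance = 1e-10)
  expect_error(signature_drift(norm, ann, character(0), "MG"), "empty")
})
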