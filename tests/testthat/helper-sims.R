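# Shared simulation fixtures, built once per test run.

sim_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = sim_cache)) assign(key, fn(), envir = sim_cache)
  get(key, envir = sim_cache)
}

# Full study-condition simulations (published rod totals); shared between
# the recovery tests and several property tests.
human_sim <- function() cached("human", function()
  simulate_retina(default_study_config("human", seed = 1)))
macaque_sim <- function() cached("macaque", function()
  simulate_retina(default_study_config("macaque", seed = 1)))
human_norm <- function() cached("human_norm", function()
  normalize_counts(human_sim()$matrix))
macaque_norm <- function() cached("macaque_norm", function()
  normalize_counts(macaque_sim()$matrix))

# Scaled-down human config for cheap unit tests: same structure, ~1/10 cells.
# Below 400 genes the planted-trend lists shrink to fit the filler space.
small_config <- function(seed = 1, n_genes = 600, ...) {
  cfg <- default_study_config("human", seed = seed, n_genes = max(n_genes, 600))
  cfg$n_genes <- as.integer(n_genes)
  if (n_genes < 400)
    cfg$planted_trends <- list(n_up = 10L, n_down = 15L, per_stage_log_fold = 1.0)
  shrink <- function(n) as.integer(ceiling(n / 10))
  for (ct in names(cfg$cell_types)) {
    cfg$cell_types[[ct]]$n_fovea <- shrink(cfg$cell_types[[ct]]$n_fovea)
    cfg$cell_types[[ct]]$n_periphery <- shrink(cfg$cell_types[[ct]]$n_periphery)
  }
  extra <- list(...)
  for (nm in names(extra)) cfg[[nm]] <- extra[[nm]]
  cfg
}

small_sim <- function() cached("small", function()
  simulate_retina(small_config(seed = 7)))
small_norm <- function() cached("small_norm", function()
  normalize_counts(small_sim()$matrix))

# Tiny hand-buildable CellMatrix.
toy_matrix <- function(counts, ages = NULL, regions = NULL, species = "human") {
  n <- ncol(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("c%03d", seq_len(n))
  cell_matrix(counts, data.frame(
    barcode = colnames(counts), donor_id = "D1", species = species,
    age_years = if (is.null(ages)) 35 else ages,
    region = if (is.null(regions)) "fovea" else regions))
}

# Negative-binomial toy counts with one planted fold change.
nb_toy <- function(n_genes, n_a, n_b, planted_gene = NULL, fold = 1,
                   base_mu = 10, size = 4, seed = 1) {
  set.seed(seed)
  mu <- matrix(base_mu, n_genes, n_a + n_b)
  if (!is.null(planted_gene)) mu[planted_gene, seq_len(n_a)] <- base_mu * fold
  counts <- matrix(rnbinom(length(mu), size = size, mu = mu), n_genes)
  toy_matrix(counts)
}
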