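#' Generator configuration
#'
#' Bundles every knob of the synthetic retina generator: gene universe size,
#' donor panel, per-type cell allocations and markers, the rod MYO9A+/-
#' mixture and its regional placement, the stage-dependent horizontal-cell
#' H1/H2 mixture, planted monotone trend genes, planted ligand-receptor
#' aging signals, and the negative-binomial noise model.
#'
#' @param n_genes total genes in the universe (markers + planted + filler).
#' @param donors data.frame `donor_id`, `species`, `age_years`.
#' @param cell_types named list; each element a list with `markers`
#'   (character), `marker_log_fold` (log-scale elevation of markers in that
#'   type), `n_fovea`, `n_periphery` (total cells per region, split across
#'   donors by largest remainder).
#' @param rod_subtype_mix list `frac_myo9a_neg` (fraction of rods lacking the
#'   MYO9A transcript), `frac_neg_in_periphery` (regional placement of the
#'   MYO9A- class; `NULL` = proportional to rod region sizes),
#'   `myo9a_log_fold` (MYO9A elevation in MYO9A+ rods).
#' @param hc_mix data.frame `region`, `stage` (a stage name or `"all"`),
#'   `frac_h2`: horizontal-cell H2 fraction per region and donor stage.
#' @param hc_subtype_log_fold elevation of LHX1/PCP4 in H1 cells and
#'   ISL1/CALB1 in H2 cells.
#' @param planted_trends list `n_up`, `n_down`, `per_stage_log_fold`: filler
#'   genes whose log-mean shifts by `per_stage_log_fold` per age stage
#'   (adult -> mid -> aging) in every cell, up or down.
#' @param lr_signals data.frame `ligand`, `receptor`, `sender`, `receiver`,
#'   `aged_log_fold`: ligand shifted in aged sender cells, receptor in aged
#'   receiver cells; both genes get `base_log_fold` in their home type at
#'   all stages so they pass expression filters.
#' @param lr_base_log_fold baseline elevation of LR genes in their home types.
#' @param regional_programs optional data.frame `cell_type`, `region`,
#'   `gene`, `log_fold`: region-specific expression programs (e.g. foveal
#'   vs peripheral glial genes), elevated in the given type and region at
#'   all ages.
#' @param nb_dispersion negative-binomial size parameter (shared).
#' @param base_mean background mean count per gene per cell.
#' @param depth_sigma sd of the per-cell lognormal library-depth factor.
#' @param stage_map donor staging used for stage-dependent structure.
#' @param seed mandatory integer seed.
#' @return validated object of class `GeneratorConfig`.
#' @export
generator_config <- function(n_genes, donors, cell_types,
                             rod_subtype_mix = NULL,
                             hc_mix = NULL,
                             hc_subtype_log_fold = 5.1,
                             planted_trends = list(n_up = 0, n_down = 0,
                                                   per_stage_log_fold = 1.0),
                             lr_signals = NULL,
                             lr_base_log_fold = 1.0,
                             regional_programs = NULL,
                             nb_dispersion = 4,
                             base_mean = 0.3,
                             depth_sigma = 0.3,
                             stage_map = default_stage_map(),
                             seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- structure(
    list(n_genes = as.integer(n_genes), donors = as.data.frame(donors),
         cell_types = cell_types, rod_subtype_mix = rod_subtype_mix,
         hc_mix = if (is.null(hc_mix)) NULL else as.data.frame(hc_mix),
         hc_subtype_log_fold = hc_subtype_log_fold,
         planted_trends = planted_trends,
         lr_signals = if (is.null(lr_signals)) NULL else as.data.frame(lr_signals),
         lr_base_log_fold = lr_base_log_fold,
         regional_programs = if (is.null(regional_programs)) NULL else
           as.data.frame(regional_programs),
         nb_dispersion = nb_dispersion, base_mean = base_mean,
         depth_sigma = depth_sigma, stage_map = stage_map,
         seed = as.integer(seed)),
    class = "GeneratorConfig")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  if (cfg$n_genes < 1L) stop("n_genes must be positive")
  if (!all(c("donor_id", "species", "age_years") %in% names(cfg$donors)))
    stop("donors needs donor_id, species, age_years")
  if (!all(cfg$donors$species %in% SPECIES)) stop("unknown species in donors")
  for (ct in names(cfg$cell_types)) {
    sp <- cfg$cell_types[[ct]]
    if (sp$n_fovea < 0 || sp$n_periphery < 0)
      stop("negative cell count for type ", ct)
    if (is.null(sp$markers) || !length(sp$markers))
      stop("cell type ", ct, " has no markers")
  }
  frac_ok <- function(f) is.null(f) || (is.numeric(f) && f >= 0 && f <= 1)
  rs <- cfg$rod_subtype_mix
  if (!is.null(rs)) {
    if (!frac_ok(rs$frac_myo9a_neg) || !frac_ok(rs$frac_neg_in_periphery))
      stop("rod subtype fractions must lie in [0, 1]")
    if (!"rod" %in% names(cfg$cell_types))
      stop("rod_subtype_mix given but no rod cell type configured")
  }
  if (!is.null(cfg$hc_mix)) {
    if (!all(cfg$hc_mix$frac_h2 >= 0 & cfg$hc_mix$frac_h2 <= 1))
      stop("hc_mix fractions must lie in [0, 1]")
    if (!"HC" %in% names(cfg$cell_types))
      stop("hc_mix given but no HC cell type configured")
  }
  pt <- cfg$planted_trends
  if (pt$n_up + pt$n_down > cfg$n_genes)
    stop("planted gene counts exceed n_genes")
  if (cfg$nb_dispersion <= 0 || cfg$base_mean <= 0)
    stop("nb_dispersion and base_mean must be positive")
  invisible(cfg)
}

# Largest-remainder apportionment of `total` integer units over weights.
apportion <- function(total, weights) {
  k <- length(weights)
  if (total == 0L || k == 0L) return(integer(k))
  if (sum(weights) == 0) weights <- rep(1, k)
  q <- total * weights / sum(weights)
  f <- floor(q)
  r <- as.integer(total - sum(f))
  if (r > 0L) {
    o <- order(q - f, decreasing = TRUE)
    f[o[seq_len(r)]] <- f[o[seq_len(r)]] + 1
  }
  as.integer(f)
}

#' Default study-condition configuration
#'
#' A [generator_config()] pre-filled with the atlas study's printed
#' conditions for one species: the full donor panel (one adult, two mid-age
#' and two aged humans; five macaques aged 2-23), the published rod totals
#' (16,686 human / 36,904 macaque), the printed rod-subtype mixtures
#' (MYO9A- fraction 36.9% human / 4.7% macaque, the latter with 98.6%
#' peripheral placement), the horizontal-cell mixtures that reproduce the
#' printed 92.0% foveal H1 (human), 60.0% (macaque) and the pooled
#' stage-wise H2 fractions 52.3% (mid-age) and 14.2% (aged), 87 planted
#' up-trend and 121 planted down-trend genes, and a small set of planted
#' VEGFA-centred ligand-receptor aging signals.
#'
#' @param species `"human"` or `"macaque"`.
#' @param seed integer seed (default 1).
#' @param n_genes gene universe size (default 2000).
#' @return a `GeneratorConfig`.
#' @export
default_study_config <- function(species, seed = 1, n_genes = 2000) {
  species <- match.arg(species, SPECIES)
  if (species == "human") {
    donors <- data.frame(
      donor_id = c("H35", "H52", "H63", "H86", "H87"),
      species = "human",
      age_years = c(35, 52, 63, 86, 87))
    rod_mix <- list(frac_myo9a_neg = 0.369, frac_neg_in_periphery = 0.75,
                    myo9a_log_fold = 5.1)
    # Foveal H2 pinned at 8% in every stage; the peripheral fraction carries
    # the stage dependence so that pooled stage H2 equals the printed
    # 52.3% (mid-age) and 14.2% (aged) with equal HC numbers per region.
    hc_mix <- data.frame(
      region = c("fovea", "periphery", "periphery", "periphery"),
      stage = c("all", "adult", "mid-age", "aging"),
      frac_h2 = c(0.08, 0.60, 0.966, 0.204))
    n_rod <- 16686L
  } else {
    donors <- data.frame(
      donor_id = c("M2", "M4", "M5", "M9", "M23"),
      species = "macaque",
      age_years = c(2, 4, 5, 9, 23))
    rod_mix <- list(frac_myo9a_neg = 0.047, frac_neg_in_periphery = 0.986,
                    myo9a_log_fold = 5.1)
    hc_mix <- data.frame(
      region = c("fovea", "periphery"),
      stage = c("all", "all"),
      frac_h2 = c(0.40, 0.60))
    n_rod <- 36904L
  }
  cell_types <- list(
    rod = list(markers = c("NRL", "RHO", "GNGT1", "CNGA1"),
               marker_log_fold = 3,
               n_fovea = as.integer(round(n_rod * 0.25)),
               n_periphery = n_rod - as.integer(round(n_rod * 0.25))),
    cone = list(markers = c("ARR3", "PDE6H", "GNAT2", "OPN1SW"),
                marker_log_fold = 3, n_fovea = 1000L, n_periphery = 500L),
    HC = list(markers = c("ONECUT1", "ONECUT2"),
              marker_log_fold = 3, n_fovea = 1000L, n_periphery = 1000L),
    BC = list(markers = c("VSX2", "TRPM1", "GRM6"),
              marker_log_fold = 3, n_fovea = 750L, n_periphery = 750L),
    MG = list(markers = c("RLBP1", "GLUL", "APOE", "SLC1A3"),
              marker_log_fold = 3, n_fovea = 750L, n_periphery = 750L),
    AC = list(markers = c("GAD1", "SLC6A9", "TFAP2A"),
              marker_log_fold = 3, n_fovea = 500L, n_periphery = 500L),
    microglia = list(markers = c("AIF1", "C1QA", "CX3CR1"),
                     marker_log_fold = 3, n_fovea = 250L, n_periphery = 250L))
  lr <- data.frame(
    ligand = c("VEGFA", "VEGFA", "BDNF", "TGFB1"),
    receptor = c("FLT1", "KDR", "NTRK2", "TGFBR1"),
    sender = c("MG", "BC", "MG", "microglia"),
    receiver = c("rod", "rod", "rod", "MG"),
    aged_log_fold = c(1.5, 1.5, 1.5, 1.5))
  # conserved regional programs: foveal vs peripheral Muller glia and the
  # peripheral-cone CALB1 signal; NPVF peripheral-MG expression is human-
  # specific
  fov_mg <- c("TRH", "FGF9", "DIO2", "CYP26A1", "RGR", "HTRA1")
  per_mg <- c("MT3", "MT2A", "GPX3")
  if (species == "human") per_mg <- c(per_mg, "NPVF")
  programs <- rbind(
    data.frame(cell_type = "MG", region = "fovea", gene = fov_mg, log_fold = 2),
    data.frame(cell_type = "MG", region = "periphery", gene = per_mg, log_fold = 2),
    data.frame(cell_type = "cone", region = "periphery", gene = "CALB1",
               log_fold = 1.5))
  generator_config(
    n_genes = n_genes, donors = donors, cell_types = cell_types,
    rod_subtype_mix = rod_mix, hc_mix = hc_mix,
    planted_trends = list(n_up = 87L, n_down = 121L, per_stage_log_fold = 1.0),
    lr_signals = lr, regional_programs = programs, seed = seed)
}

# Stage index used by the trend model: adult 0, mid-age 1, aging 2;
# donors outside the stage map get 0 (no trend shift).
stage_index <- function(stage, stage_map) {
  idx <- match(stage, stage_map$stage_name) - 1L
  idx[is.na(idx)] <- 0L
  idx
}

hc_frac_lookup <- function(hc_mix, region, stage) {
  hit <- which(hc_mix$region == region & hc_mix$stage == stage)
  if (!length(hit)) hit <- which(hc_mix$region == region & hc_mix$stage == "all")
  if (!length(hit)) return(0)
  hc_mix$frac_h2[hit[1L]]
}

#' Simulate a synthetic retina dataset
#'
#' Draws negative-binomial counts under a log-linear mean model: a shared
#' background mean, marker elevation per cell type, subtype structure (rod
#' MYO9A presence/absence with configured mixing and regional placement;
#' horizontal-cell H1/H2 marker switches with stage-dependent mixing),
#' monotone per-stage shifts for planted trend genes in every cell, aged-
#' donor shifts for planted ligand-receptor signal genes in their sender and
#' receiver types, and a per-cell lognormal library-depth factor. Subtype
#' counts are allocated by largest-remainder rounding of the configured
#' fractions; which cells receive which label is randomized under the seed.
#'
#' @param config a [generator_config()].
#' @return list with `matrix` (a [cell_matrix()] whose `truth` holds per-cell
#'   labels) and `truth`: list with `cells` (barcode, cell_type, subtype,
#'   stage), `up_genes`, `down_genes`, `lr_signals`, `markers`, `config`.
#' @export
simulate_retina <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  donors <- config$donors
  donors$stage <- vapply(donors$age_years, assign_stage, "",
                         stage_map = config$stage_map)
  donors$stage_idx <- stage_index(donors$stage, config$stage_map)

  ## ---- gene universe -------------------------------------------------
  marker_genes <- unique(unlist(lapply(config$cell_types, `[[`, "markers")))
  special <- character(0)
  if (!is.null(config$rod_subtype_mix)) special <- c(special, "MYO9A")
  if (!is.null(config$hc_mix))
    special <- c(special, "LHX1", "PCP4", "ISL1", "CALB1")
  lr_genes <- if (is.null(config$lr_signals)) character(0) else
    unique(c(config$lr_signals$ligand, config$lr_signals$receptor))
  prog_genes <- if (is.null(config$regional_programs)) character(0) else
    unique(config$regional_programs$gene)
  named <- unique(c(marker_genes, special, lr_genes, prog_genes))
  n_fill <- config$n_genes - length(named)
  if (n_fill < config$planted_trends$n_up + config$planted_trends$n_down)
    stop("n_genes too small for named plus planted genes")
  fillers <- sprintf("G%04d", seq_len(n_fill))
  gene_ids <- c(named, fillers)
  up_genes <- fillers[seq_len(config$planted_trends$n_up)]
  down_genes <- fillers[config$planted_trends$n_up +
                          seq_len(config$planted_trends$n_down)]
  trend_dir <- numeric(config$n_genes)
  names(trend_dir) <- gene_ids
  trend_dir[up_genes] <- 1
  trend_dir[down_genes] <- -1

  ## ---- cell groups ---------------------------------------------------
  groups <- list()
  for (ct in names(config$cell_types)) {
    sp <- config$cell_types[[ct]]
    for (region in REGIONS) {
      total <- if (region == "fovea") sp$n_fovea else sp$n_periphery
      per_donor <- apportion(total, rep(1, nrow(donors)))
      for (d in seq_len(nrow(donors))) {
        if (per_donor[d] == 0L) next
        groups[[length(groups) + 1L]] <- list(
          cell_type = ct, region = region, donor = d, n = per_donor[d])
      }
    }
  }

  ## ---- subtype allocation --------------------------------------------
  # Rods: species-level MYO9A- total, split fovea/periphery by the placement
  # fraction, then spread over donor groups by largest remainder.
  rod_neg_by_group <- integer(length(groups))
  rs <- config$rod_subtype_mix
  if (!is.null(rs)) {
    is_rod <- vapply(groups, function(g) g$cell_type == "rod", TRUE)
    rod_n <- vapply(groups, function(g) if (g$cell_type == "rod") g$n else 0L, 0L)
    n_rod <- sum(rod_n)
    n_neg <- as.integer(round(rs$frac_myo9a_neg * n_rod))
    per_share <- sum(rod_n[is_rod &
      vapply(groups, function(g) g$region == "periphery", TRUE)]) / max(n_rod, 1L)
    f_per <- if (is.null(rs$frac_neg_in_periphery)) per_share else rs$frac_neg_in_periphery
    n_neg_per <- min(as.integer(round(f_per * n_neg)), n_neg)
    for (region in REGIONS) {
      tgt <- if (region == "periphery") n_neg_per else n_neg - n_neg_per
      gi <- which(is_rod & vapply(groups, function(g) g$region == region, TRUE))
      if (!length(gi)) next
      alloc <- apportion(tgt, rod_n[gi])
      alloc <- pmin(alloc, rod_n[gi])  # cannot exceed group size
      rod_neg_by_group[gi] <- alloc
    }
  }

  ## ---- per-group sampling --------------------------------------------
  base_log <- log(config$base_mean)
  i_list <- list(); j_list <- list(); x_list <- list()
  meta_list <- list(); truth_list <- list()
  offset <- 0L
  cell_counter <- 0L
  prefix <- if (donors$species[1] == "human") "HUM" else "MAC"

  type_log_mu <- function(ct) {
    lmu <- rep(base_log, config$n_genes)
    names(lmu) <- gene_ids
    sp <- config$cell_types[[ct]]
    lmu[sp$markers] <- lmu[sp$markers] + sp$marker_log_fold
    if (!is.null(config$lr_signals)) {
      ls <- config$lr_signals
      lig <- unique(ls$ligand[ls$sender == ct])
      rec <- unique(ls$receptor[ls$receiver == ct])
      lmu[lig] <- lmu[lig] + config$lr_base_log_fold
      lmu[rec] <- lmu[rec] + config$lr_base_log_fold
    }
    lmu
  }

  sample_block <- function(log_mu, n_cells) {
    depth <- exp(stats::rnorm(n_cells, 0, config$depth_sigma))
    mu <- exp(log_mu) %o% depth
    matrix(stats::rnbinom(length(mu), size = config$nb_dispersion, mu = mu),
           nrow = config$n_genes)
  }

  emit <- function(counts, g, subtype) {
    n <- ncol(counts)
    ids <- sprintf("%s-%06d", prefix, cell_counter + seq_len(n))
    cell_counter <<- cell_counter + n
    nz <- which(counts != 0)
    i_list[[length(i_list) + 1L]] <<- ((nz - 1L) %% config$n_genes) + 1L
    j_list[[length(j_list) + 1L]] <<- ((nz - 1L) %/% config$n_genes) + 1L + offset
    x_list[[length(x_list) + 1L]] <<- counts[nz]
    offset <<- offset + n
    d <- donors[g$donor, ]
    meta_list[[length(meta_list) + 1L]] <<- data.frame(
      barcode = ids, donor_id = d$donor_id, species = d$species,
      age_years = d$age_years, region = g$region, stringsAsFactors = FALSE)
    truth_list[[length(truth_list) + 1L]] <<- data.frame(
      barcode = ids, cell_type = g$cell_type,
      subtype = if (is.null(subtype)) NA_character_ else subtype,
      stage = d$stage, stringsAsFactors = FALSE)
  }

  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    d <- donors[g$donor, ]
    lmu <- type_log_mu(g$cell_type)
    # monotone per-stage trend, all cells
    lmu <- lmu + trend_dir * config$planted_trends$per_stage_log_fold * d$stage_idx
    # region-specific programs, constant across ages
    if (!is.null(config$regional_programs)) {
      rp <- config$regional_programs
      hit <- rp$cell_type == g$cell_type & rp$region == g$region
      lmu[rp$gene[hit]] <- lmu[rp$gene[hit]] + rp$log_fold[hit]
    }
    # aged-donor LR shifts in sender/receiver types
    if (!is.null(config$lr_signals) && d$stage == "aging") {
      ls <- config$lr_signals
      for (k in seq_len(nrow(ls))) {
        if (ls$sender[k] == g$cell_type)
          lmu[ls$ligand[k]] <- lmu[ls$ligand[k]] + ls$aged_log_fold[k]
        if (ls$receiver[k] == g$cell_type)
          lmu[ls$receptor[k]] <- lmu[ls$receptor[k]] + ls$aged_log_fold[k]
      }
    }
    if (g$cell_type == "rod" && !is.null(rs)) {
      n_neg <- rod_neg_by_group[gi]
      sub <- sample(c(rep("MYO9A-", n_neg), rep("MYO9A+", g$n - n_neg)))
      for (st in c("MYO9A+", "MYO9A-")) {
        n_st <- sum(sub == st)
        if (n_st == 0L) next
        lmu_st <- lmu
        if (st == "MYO9A+") lmu_st["MYO9A"] <- lmu_st["MYO9A"] + rs$myo9a_log_fold
        else lmu_st["MYO9A"] <- -Inf  # transcript absent
        emit(sample_block(lmu_st, n_st), g, st)
      }
    } else if (g$cell_type == "HC" && !is.null(config$hc_mix)) {
      frac_h2 <- hc_frac_lookup(config$hc_mix, g$region, d$stage)
      n_h2 <- as.integer(round(frac_h2 * g$n))
      for (st in c("H1", "H2")) {
        n_st <- if (st == "H2") n_h2 else g$n - n_h2
        if (n_st == 0L) next
        lmu_st <- lmu
        mk <- if (st == "H1") c("LHX1", "PCP4") else c("ISL1", "CALB1")
        lmu_st[mk] <- lmu_st[mk] + config$hc_subtype_log_fold
        emit(sample_block(lmu_st, n_st), g, st)
      }
    } else {
      emit(sample_block(lmu, g$n), g, NULL)
    }
  }

  meta <- do.call(rbind, meta_list)
  truth_cells <- do.call(rbind, truth_list)
  counts <- Matrix::sparseMatrix(
    i = unlist(i_list), j = unlist(j_list), x = unlist(x_list),
    dims = c(config$n_genes, nrow(meta)),
    dimnames = list(gene_ids, meta$barcode))
  mat <- cell_matrix(counts, meta, truth = truth_cells)
  truth <- list(cells = truth_cells, up_genes = up_genes,
                down_genes = down_genes, lr_signals = config$lr_signals,
                markers = lapply(config$cell_types, `[[`, "markers"),
                config = config)
  list(matrix = mat, truth = truth)
}

#' Write a simulated dataset plus ground truth to disk
#'
#' Emits the standard MTX/TSV layout via [write_matrix()] (including
#' `truth.tsv`) together with a YAML snapshot of the generator configuration.
#'
#' @param sim result of [simulate_retina()].
#' @param dir_path output directory.
#' @return `dir_path`, invisibly.
#' @export
write_simulation <- function(sim, dir_path) {
  write_matrix(sim$matrix, dir_path)
  cfg <- sim$truth$config
  snap <- list(
    n_genes = cfg$n_genes, seed = cfg$seed, base_mean = cfg$base_mean,
    nb_dispersion = cfg$nb_dispersion, depth_sigma = cfg$depth_sigma,
    donors = as.list(cfg$donors$donor_id),
    up_genes = as.list(sim$truth$up_genes),
    down_genes = as.list(sim$truth$down_genes))
  yaml::write_yaml(snap, file.path(dir_path, "config.yaml"))
  invisible(dir_path)
}
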