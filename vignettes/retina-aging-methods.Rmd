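---
title: "Methods: region- and age-resolved analysis of the primate retina"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region- and age-resolved analysis of the primate retina}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`retinaAging` implements the computational stages of a fovea/periphery,
multi-age single-cell retina analysis: cell-type annotation with rod and
horizontal-cell subtype classification and proportion tracking, a monotone
aging-trend screen, a gene-set pseudo-aging score with regional
trajectories, a ligand–receptor differential communication network, a
disease-gene expression/enrichment map, and cross-species cell-type
correlation. Every stage is exercisable on synthetic data with ground
truth, generated by the package itself.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the design decisions taken where the
problem was genuinely open. It states no empirical result beyond what the
test suite and `scripts/acceptance.R` recompute.

# Input model and normalization

The universal input is a `CellMatrix`: sparse integer counts (genes ×
cells) plus per-cell metadata — donor, species (`human`/`macaque`), age in
years (real-valued; an 8-day infant encodes as 0.02), and region
(`fovea`/`periphery`). I/O uses the CellRanger v3 triplet (`matrix.mtx` in
Matrix Market coordinate-integer format, `features.tsv`, `barcodes.tsv`)
plus a `cells.tsv` metadata table; `read_matrix()`/`write_matrix()`
round-trip exactly.

Normalization is the droplet convention: counts per `scale_total`
(default 10,000) per cell, then `log1p` (natural log). The convention is a
package decision — expression comparisons in this kind of study presuppose
depth normalization but rarely state one. All downstream linear-scale
means de-log with `expm1` and use a pseudocount of 1, so fold changes are
finite for genes absent from a group.

Differential expression is a two-sided Wilcoxon rank-sum test on
normalized values with Benjamini–Hochberg correction and a 10%
detection-fraction gate (gene tested when detected in ≥10% of at least one
group). The test is computed vectorized with the tie-corrected normal
approximation plus continuity correction — the regime is always hundreds
to thousands of cells per group — and is verified against
`stats::wilcox.test` in the suite. Type-I error under label permutation is
checked at the nominal level.

# The synthetic-data generator

Counts are negative binomial with a log-linear mean:

- background mean `base_mean = 0.3` per gene per cell, shared dispersion
  `size = 4` (moderate droplet-like overdispersion), and a per-cell
  lognormal depth factor (σ = 0.3) so normalization is actually exercised;
- cell-type markers elevated additively on the log mean
  (`marker_log_fold = 3`);
- rod subtype structure: MYO9A+ rods carry the transcript at a high mean
  (log-fold 5.1 over background), MYO9A− rods lack it entirely (mean 0) —
  presence/absence of a transcript, not a graded shift;
- horizontal cells switch marker blocks: H1 elevates LHX1/PCP4, H2
  elevates ISL1/CALB1 (log-fold 5.1);
- region-specific programs constant across ages: foveal Müller-glia genes
  (TRH, FGF9, DIO2, CYP26A1, RGR, HTRA1) and peripheral ones (MT3, MT2A,
  GPX3, plus NPVF in human only), and peripheral-cone CALB1 (log-folds
  2 and 1.5) — the conserved regional structure that cross-species
  centroid correlation feeds on;
- planted trend genes shift by `per_stage_log_fold = 1.0` per age stage
  (adult → mid-age → aging) in every cell, up or down;
- planted ligand–receptor signals elevate the ligand in its sender type
  and the receptor in its receiver type in aged donors (log-fold 1.5, on
  top of a constant home-type elevation of 1.0).

Subtype *counts* are allocated by largest-remainder rounding of the
configured fractions; which cells receive which label is randomized under
the seed. The configured fraction is a study condition, not an estimand of
the generator, so it is honored exactly up to integer rounding rather than
re-sampled binomially.

`default_study_config()` pins the study conditions per species: the
five-donor human panel (ages 35; 52, 63; 86, 87 — one adult, two mid-age,
two aged) and a five-donor macaque panel (ages 2–23), 16,686 human and
36,904 macaque rods, human MYO9A− fraction 0.369 (macaque 0.047 with
98.6% peripheral placement), and 87 up / 121 down planted trend genes in a
2,000-gene universe.

The published horizontal-cell numbers come from different slices of the
data: 92.0% of foveal HCs are H1 (60.0% in macaque), while the overall H2
fraction falls from 52.3% (mid-age) to 14.2% (aged). With equal HC counts
per region, the default config reconciles all three by fixing foveal H2 at
8% in every stage and letting the peripheral H2 fraction carry the stage
dependence (adult 0.60, mid-age 0.966, aged 0.204): pooled foveal H1 is
then 92.0% and pooled stage-wise H2 is 52.3% / 14.2% exactly.

What the generator does *not* emulate: ambient RNA, doublets, batch
effects, gene–gene correlation beyond condition structure, and spatial
organization. Passing recovery tests therefore demonstrates that the
estimators invert the generative structure they target — not robustness to
every artifact of real droplet data.

# Annotation and subtype classification

`cluster_cells()` is the conventional pipeline — highly-variable-gene
selection (`n_hvg`, default 2000), per-gene z-scaling, top 30 principal
components, a k = 15 nearest-neighbour graph, Louvain communities
(resolution 1.0 default, exposed) — deterministic under a fixed seed. The
exact kNN search is quadratic in cells; it is intended for the
10³–10⁴-cell scales used here. On the synthetic data the HVG count
matters more than on real data: the generator's filler genes are pure
noise, so keeping roughly the top 5–10% most variable genes (e.g.
`n_hvg = 100` of 2,000) is the right analogue of the usual
2,000-of-20,000 selection, and the resolution parameter decides whether
small populations keep their own community (too low merges them; the
workflow drivers use the defaults plus `n_hvg` scaled this way).

`score_cell_types()` z-scores cluster-mean expression per gene across
clusters; a cluster's score for a type is the mean z over the type's panel
markers, the cluster takes the argmax label, and cells inherit it
(cluster-level labeling mirrors the cluster-then-annotate flow; per-cluster
scores are kept for audit). Ties break lexicographically on the type name
and set a flag — reproducibility over arbitrariness.

Rod subtypes use a detection threshold: MYO9A+ iff raw count ≥ 1
(equivalently, normalized value > 0). A study inferring ± status from
scRNA-seq gives no cutoff; count ≥ 1 is the natural reading and its
behavior under artificial dropout is characterized in the suite
(misclassification equals the injected dropout rate). The split is applied
per cell, with cluster-level audit available. HC subtypes take the argmax
of mean z-scored expression of the H1 vs H2 marker pairs, tie to H1 with a
flag. The OTX2⁺RLBP1⁺-style co-positive population is a query
(`co_positive()`: count ≥ 1 in every listed gene), not a dedicated
classifier.

`estimate_proportions()` reports per-group label proportions with
percentile bootstrap 95% CIs from resampling cells within the group
(n ≥ 200 replicates enforced; coverage checked against binomial draws).

# Monotone aging-trend screen

Donors are binned by the stage map adult [18, 45], mid-age [46, 70], aging
[71, 120]; ages outside every interval are `"unstaged"`. "Continuously
increased" is formalized as: strictly ordered stage means, both adjacent
Wilcoxon contrasts (cells pooled within stage) BH-significant at
α = 0.05, and both adjacent log2 fold changes ≥ 0.25 ("down" mirrored).
The source analyses state no explicit criterion; requiring significance of
*both* adjacent steps plus an effect-size floor is the strict reading, and
the log2FC floor is what keeps the screen's false-discovery behavior
stable when normalization induces tiny but significant composition shifts
at large cell numbers. Directionality is antisymmetric by construction and
checked as such.

# Pseudo-aging score and trajectories

The score is the weighted mean z-scored expression of the up genes minus
that of the down genes, min–max rescaled to [0, 1] over the dataset
(order-preserving). The original study adapted a published maturation-
scoring algorithm whose exact weighting is not recoverable from the text;
the implemented definition is the simplest faithful reading, with a weight
hook (e.g. correlation-with-age weights) for closer emulations. The
packaged gene set is a synthetic stand-in aligned with the generator's
planted trends; `read_aging_geneset()` accepts the two-column
(gene, direction) export of curated ageing-gene resources for real use.

Trajectories are local-linear (degree-1) smooths of score vs donor age —
Gaussian kernel, bandwidth half the age range — on a 25-point grid. The
uncertainty band is a simultaneous 95% sup-t band built from 500
donor-stratified bootstrap resamples of cells: the band half-width at each
grid point is the bootstrap SD scaled by the 95% quantile of the bootstrap
sup of the standardized curve deviation. A pointwise percentile band was
measured at ≈0.86 joint coverage of a linear generating curve across the
grid; the sup-t construction covers the whole curve (measured ≈0.97),
which is the property a plotted confidence shadow is read as having.
Several hundred replicates are needed for stable tail quantiles, hence the
500 default. `fit_trajectory()` is exact on constant input and reproduces
the sign of planted linear trends at every grid point.

The fovea-vs-periphery gradient test compares mean fitted curves on a
shared grid (`delta = mean(fit_fovea − fit_periphery)`); the null
distribution permutes region labels among cells *within donor* (the
exchangeable unit), with the (1 + x)/(n + 1) two-sided p-value. Null
uniformity is verified by KS test in the suite.

# Communication network

Per cell type, `de_magnitude()` is |log2FC| of aging vs adult (pseudocount
1 on de-logged means), z-scaled across that type's genes; "scaled
magnitude" is not further specified in the source, and a within-type
z-scale makes magnitudes comparable across types of different noise
levels. A signed variant is a flag. Edges connect (ligand, sender) to
(receptor, receiver) for every pair in the LR database with both genes
detected in ≥10% of their home type (the conventional communication-
analysis gate); the edge score is the sum of the two node magnitudes, and
`top_k_edges()` keeps the 100 highest with lexicographic tie-breaking on
pair id, then sender, then receiver. The shipped LR table is a small
curated fixture (VEGFA and its receptors among them); any two-column TSV
is accepted. Per-pair permutation p-values are out of scope — the analysis
reports scores, not tests.

# Disease map

"Aggregated expression" is formalized as: per gene, mean normalized
expression per (cell type × region) group, z-scaled across groups; a
disease's score in a group is the mean z over its present genes — which
makes scores comparable across diseases of different set sizes. Diseases
with no present genes yield `NA` rows, never silent zeros. The bootstrap
test resamples *genes* (size-matched sets from the expressed pool), the
standard construction for gene-set specificity: p = (1 + #{null ≥
observed}) / (B + 1), bounded below by 1/(B + 1), seed-reproducible, with
BH across all (disease × group) rows reported alongside. The shipped
178-gene / 55-disease table is a synthetic stand-in with the catalogue's
shape (`disease_genes_synthetic.tsv`); `read_disease_table()` accepts the
real export format.

# Cross-species correlation

A one-to-one ortholog table restricts both matrices to the shared gene
space (≥50 genes enforced); cell-type centroids are mean normalized
expression; correlation is Spearman by default (Pearson by flag) — the
source names neither. Band labels follow the published legend read
literally: low < 0.3, mid [0.3, 0.5], high > 0.5, with 0.3 itself falling
in "mid" and boundaries tested exhaustively. Joint matrix factorization
across species is out of scope (published tooling, not re-implemented).

# Problem sizes and determinism

The test suite and the acceptance script regenerate everything from code:
the full study-condition simulations (≈25k human cells, ≈45k macaque
cells, 2,000 genes) for the recovery checks, and ~1/10-scale versions of
the same structure for unit and calibration tests. Calibration suites use
10 null simulations (trend screen), 50–60 replicates (band coverage,
gradient-test uniformity), 100 random gene sets at B = 500 (enrichment),
and 200 replicates (proportion-CI coverage). Every stochastic step takes
an explicit integer seed, and seeded helpers restore the caller's RNG
state, so results are bit-reproducible for a given seed.

# Known limitations

- The generator's independence across genes means co-expression-based
  analyses (e.g. network module discovery) cannot be validated here and
  are not implemented.
- `cluster_cells()` uses exact distances; for atlases beyond ~10⁴ cells an
  approximate-neighbour backend would be needed.
- The pseudo-aging score is score-vs-chronological-age; no latent
  pseudotime is inferred.
- Recovery tolerances (±1–2 percentage points on subtype fractions, exact
  planted-gene counts) are statements about the estimators under the
  generator's assumptions, not about real tissue.
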