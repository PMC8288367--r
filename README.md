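# retinaAging

Analysis toolkit for studying how the primate retina ages, region by
region and cell type by cell type, from single-cell RNA-seq count
matrices annotated with donor, species (human/macaque), age and region
(fovea/periphery). It is written for computational biologists who want
the bespoke statistics of a fovea/periphery multi-age retina atlas as
tested, reusable functions, exercisable end-to-end on synthetic data with
known ground truth.

## What it computes

- **Annotation and subtypes.** Marker-panel scoring of clusters
  (z-scored cluster means, argmax label), rod subtype classification by
  MYO9A transcript detection (count ≥ 1 ⇒ MYO9A+), horizontal-cell H1/H2
  classification by the LHX1/PCP4-vs-ISL1/CALB1 score rule, and label
  proportions with percentile-bootstrap 95% CIs.
- **Monotone aging trends.** Donors binned into adult [18,45],
  mid-age [46,70], aging [71,120]; a gene is "up" when its stage means
  strictly increase and both adjacent Wilcoxon contrasts pass BH
  fdr ≤ 0.05 with |log2FC| ≥ 0.25 (pseudocount 1 on de-logged means);
  "down" mirrored.
- **Pseudo-aging score.** For an aging gene set, score = mean weighted
  z-expression over up genes − the same over down genes, min–max rescaled
  to [0,1]; local-linear score-vs-age trajectories per region with a
  simultaneous 95% bootstrap band, and a within-donor permutation test of
  the fovea−periphery gap.
- **Ligand–receptor communication.** Per cell type, |log2FC| of aging vs
  adult z-scaled across genes; edges (ligand, sender) → (receptor,
  receiver) scored as the sum of the two node magnitudes, gated at 10%
  detection, filtered to the top 100.
- **Disease map.** Disease-gene sets aggregated as mean per-gene group
  z-scores over cell type × region (or age stage) groups, with a
  size-matched random-gene-set bootstrap p-value, p = (1 + #{null ≥
  obs})/(B + 1), BH-adjusted.
- **Cross-species comparison.** One-to-one ortholog restriction, Spearman
  correlation of cell-type centroids, banded low < 0.3 ≤ mid ≤ 0.5 < high.
- **Synthetic data.** A negative-binomial generator
  (`simulate_retina()`) that plants all of the structure above —
  marker elevation, MYO9A± and H1/H2 mixtures with regional and
  stage-dependent composition, monotone trend genes, aged-donor
  ligand–receptor shifts — and returns per-cell/per-gene ground truth.
  `default_study_config("human")` / `("macaque")` pin the published study
  conditions (16,686 / 36,904 rods; MYO9A− fractions 36.9% / 4.7% with
  98.6% peripheral placement in macaque; foveal H1 92% / 60%; stage-wise
  H2 52.3% → 14.2%; 87 up + 121 down trend genes in 2,000 genes).

## Worked example

```r
library(retinaAging)

sim  <- simulate_retina(default_study_config("human", seed = 1))
norm <- normalize_counts(sim$matrix)                  # log1p CP10k

ann <- annotation_from_truth(sim$matrix)              # start from true types
ann <- classify_rod_subtype(norm, ann)                # MYO9A detection rule
rods <- ann$cells$cell_type == "rod"
100 * mean(ann$cells$subtype[rods] == "MYO9A-")
#> [1] 36.90519

trends <- detect_monotone_genes(norm, alpha = 0.05, min_log2fc = 0.25)
table(trends$direction)
#>
#>  down  none    up
#>   121  1792    87
```

The first number is the percentage of the 16,686 simulated human rods
that the detection-threshold classifier calls MYO9A−, recovering the
36.9% mixture the dataset was generated with (the residual ≈0.005 pp is
the rate at which genuinely MYO9A+ rods yield zero counts). The table
shows the monotone screen recovering exactly the 87 planted up-trend and
121 planted down-trend genes out of 2,000, with no false calls.

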