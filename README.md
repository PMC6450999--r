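# organoidHCA

High-content image phenotyping of human midbrain organoid sections in R.

Midbrain organoids grown from floor-plate neural progenitors are the
workhorse 3D model for Parkinson's disease: organoids from LRRK2-G2019S
patients show fewer and less complex midbrain dopaminergic neurons (mDANs)
and an excess of FOXA2-positive progenitors compared to healthy and
isogenic controls. Those phenotypes are read out by automated analysis of
multichannel immunofluorescence section images — Hoechst (nuclei), TH
(tyrosine hydroxylase, the mDAN marker), FOXA2, and optionally SOX2/CC3.
`organoidHCA` implements that analysis end to end, for image analysts and
stem-cell labs who want the readouts to be reproducible, configurable and
testable:

* **Nuclei segmentation** — Gaussian smoothing of the Hoechst channel,
  thresholding (Otsu / fixed / quantile per channel), identification and
  subtraction of hyper-intense pyknotic (dying) nuclei, single-nucleus
  separation by distance-transform-seeded watershed, and strict size
  exclusion (labels > 10,000 px removed).
* **Marker masks** — median filtering, thresholding, removal of connected
  components < 100 px (strict), nuclear markers restricted to the nuclei
  mask.
* **Neurite topology** — thinning of the TH mask to a 1-px skeleton and
  counting of *nodes* (merged clusters of skeleton pixels with ≥ 3
  neighbors: dendrite bifurcation points) and *links* (maximal paths
  between nodes/endpoints: branches).
* **Per-cell scoring** — a perinuclear zone per retained nucleus; a cell
  is marker-positive iff the marker covers ≥ 1% of its scoring region.
  Readouts in both standard modes: marker pixels normalized to the
  Hoechst pixel count, and positive cells as a fraction of all cells,
  including TH⁺FOXA2⁺ and TH⁻FOXA2⁺.
* **Phenotype statistics** — per-section feature tables, clustered
  (clustergram-style) heatmaps of z-scored group × day means, and
  two-way ANOVA (genotype × day, Type II SS on unbalanced data) with
  Tukey–Kramer comparisons of groups within each day.
* **Synthetic organoid sections** — a generator with exact ground truth
  (nucleus pixel sets, positivity flags, drawn neurite topology, injected
  group × day effects) driving validation, type-I-error and power studies
  — no microscopy data required.

The statistical model for each feature \(y\) at section level is the
fixed-effects two-factor ANOVA
\(y_{gds} = \mu + \alpha_g + \beta_d + (\alpha\beta)_{gd} +
\varepsilon_{gds}\) over genotype groups \(g \in\) {H, P, H-G2019S, P-GC}
and differentiation days \(d \in\) {10, 35, 70}, with Tukey HSD on the
group pairs within each day.

## Worked example

Simulate one section field, run the per-image analysis, and compare
against ground truth:

```r
library(organoidHCA)

base <- synth_params(n_cells = 60, image_shape = c(320, 320), seed = 7)
sec  <- generate_section(base)
sec$image
#> image_stack: 320 x 320 | channels: hoechst, th, foxa2

fx <- image_features(sec$image)
fx$features$th_cell_fraction      # measured TH+ cell fraction
#> [1] 0.638
sec$truth$totals$th_fraction      # ground truth
#> [1] 0.638
fx$features[c("n_nodes", "n_links")]
#> $n_nodes [1] 22   $n_links [1] 63
```

`th_cell_fraction` is the fraction of retained nuclei whose perinuclear
zone contains TH signal (here it matches the ground-truth fraction
exactly to three digits); `n_nodes`/`n_links` count bifurcations and
branches of the skeletonized TH network for the whole field.

Now a small two-group cohort with a disease effect injected at day 35
only (reduced TH fraction and branching in group P), analyzed by the full
pipeline:

```r
specs  <- pd_cohort_design(n_sections = 6, days = c(10, 35),
                           groups = c("H", "P"))
cohort <- generate_cohort(specs, base)
res    <- run_pipeline(cohort$manifest, pipeline_config(),
                       images = cohort$images)
res$anova$th_foxa2_px_fraction$table
#>        term   sumsq df statistic p_value
#> 1     group 0.03061  1      5.20  0.0337
#> 2       day 0.00774  1      1.31  0.2652
#> 3 group:day 0.02600  1      4.42  0.0485
#> 4 Residuals 0.11774 20        NA      NA
res$report$th_foxa2_px_fraction$tukey[, c("day", "contrast", "p_adj", "stars")]
#>   day contrast   p_adj stars
#> 1  10    H - P 0.90058    ns
#> 2  35    H - P 0.00567    **
```

The TH/FOXA2 double-positive signal separates the groups at day 35 but
not at day 10 — the injected pattern. `cluster_heatmap(res$features)`
adds the clustergram view; the numbered drivers under `analysis/`
(`01_simulate_cohort.R`, `02_phenotype_pipeline.R`, `03_calibration.R`)
run the same workflow from a cohort written to disk and save all tables
and figures under `results/`.

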