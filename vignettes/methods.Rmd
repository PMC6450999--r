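---
title: "High-content phenotyping of midbrain organoid sections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-content phenotyping of midbrain organoid sections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidHCA)
```

## The analysis problem

Midbrain-specific organoids grown from floor-plate neural progenitors are
sectioned, immunostained (Hoechst for nuclei, tyrosine hydroxylase (TH) for
dopaminergic neurons, FOXA2 for floor-plate identity, optionally SOX2 and
cleaved caspase-3) and imaged on a high-content microscope. The scientific
readouts are per-section aggregates: how much TH signal a section carries,
how complex the dopaminergic neurite network is (bifurcation nodes and
branch links of the skeletonized TH mask), and what fraction of cells are
FOXA2-positive progenitors that have not become TH-positive neurons.
Comparing these features between patient-derived (LRRK2-G2019S) and control
organoids across differentiation days is the phenotyping experiment this
package automates.

`organoidHCA` implements the full path from multichannel section images to
those statistics, plus a synthetic-section generator with exact ground
truth, so every stage can be validated quantitatively without microscopy
data.

## Segmentation model

**Nuclei.** The Hoechst channel is smoothed with a Gaussian filter
(`gaussian_sigma`, default 2 px — nucleus-scale smoothing at typical
high-content resolution) and thresholded. The threshold method is
configurable per channel (`otsu` by default, `fixed` or `quantile`
alternatives) because fluorescence intensity scales are instrument-specific
and no single fixed value is defensible in general.

**Pyknotic nuclei.** Condensed nuclei of dying cells are hyper-intense and
small. They are identified by a second, upper intensity threshold on the
same smoothed channel. The default is a *fixed* cut at 0.6 on the
normalized [0, 1] scale, midway between the generator's normal nuclear
intensities (0.40-0.50) and its condensed intensities (roughly twice
normal): the two populations are separable by a single threshold by
construction, and a fixed midpoint cut recovers essentially the whole
pixel set of each condensed nucleus. A quantile-based alternative is
available in the configuration, but a high in-mask quantile (e.g. the 99th
percentile) by definition selects only the top 1% of mask pixels and
therefore cannot cover the full pyknotic pixel population when condensed
nuclei make up a few percent of the mask — it under-segments exactly the
objects it is meant to capture, which is why it is not the default. The
pyknotic mask is dilated by `pyknotic_dilate` (2 px) before subtraction
from the nuclei mask so that no bright ring remnant of a condensed nucleus
survives in the viable mask.

**Single nuclei.** The subtracted nuclei mask is partitioned by a
watershed seeded at the h-maxima of the Euclidean distance transform
(suppression depth `watershed_h = 2` px, the standard remedy for
over-segmentation of mildly elliptical nuclei). Two size rules are then
applied, both strict inequalities: labels larger than 10,000 px are
removed as unresolved clumps, and labels smaller than `min_nucleus_size`
(30 px) are dropped as segmentation debris — a quality-control step of the
labelling stage, needed because threshold masks can leave small fragments
(e.g. at the edge of a subtracted pyknotic nucleus) that are not cells.

**Marker masks.** Each marker channel is median-filtered (3x3),
thresholded, and cleaned by removing connected components with strictly
fewer than 100 pixels. The removal step is defined for the nuclear and
apoptosis markers (FOXA2, SOX2, CC3); the TH mask keeps all components by
default (`th_small_removal` opts in) because thin neurite fragments are
signal, not noise, for the topology features. FOXA2 and SOX2 masks are
restricted to the nuclei mask, which matches their nuclear localization.
Components and basins use 8-connectivity in 2D by default (configurable to
4), the convention of the field's imaging toolboxes.

**3D inputs.** Sections are ~50 um thick and may be imaged as thin
stacks. The default pipeline analyzes the maximum-intensity projection of
each field; per-plane analysis is selectable (`mode = "plane"`). The
choice is surfaced in the configuration rather than hidden because
projection systematically raises pixel fractions relative to per-plane
analysis.

## Neurite topology

The TH mask is thinned to a one-pixel skeleton (Zhang-Suen two-subpass
thinning, followed by a staircase cleanup pass that deletes corner pixels
whose neighbors remain mutually connected — without it, diagonal steps
carry spurious 3-neighbor pixels and every diagonal branch inflates the
junction count). A skeleton pixel with at least three 8-neighbors is a
branch pixel; 8-adjacent branch pixels merge into a single *node*, because
thinning produces small junction clusters while the biological quantity is
the bifurcation. *Links* are the maximal skeleton paths between nodes
and/or endpoints — implemented as the connected components of the skeleton
after removing branch pixels, which is equivalent because two distinct
junction clusters are never pixel-adjacent. A pure cycle counts as one
link. Terminal spurs shorter than `prune` (3 px) attached to a junction
are removed first; free-standing short paths are kept. Spur pruning is a
declared parameter because jagged mask boundaries otherwise sprout 1-2 px
artifacts at junctions.

Both counts are validated two ways: against an independent
adjacency-graph oracle (igraph over explicit pixel-pair edges) on random
neurite masks, with exact agreement required; and against the *drawn*
topology of clean synthetic trees, where at least 95/100 random trees must
be recovered exactly (the remaining misses are genuine branch crossings
that create real extra junctions in the mask, not counting errors).

## Per-cell scoring

Marker expression is quantified in the two standard modes. Mode (i):
positive marker pixels divided by the Hoechst (nuclei) mask pixel count,
including the TH-and-FOXA2 overlap and the FOXA2-without-TH set (these
are the "signal" readouts; note they are ratios to nuclear area and can
exceed 1 for a cytoplasm+neurite marker). Mode (ii): per-cell calls. For
every retained nucleus a perinuclear zone is grown (`ring_width = 3` px of
iterated 8-neighbor dilation — perinuclear cytoplasm at typical
high-content magnification); where rings of adjacent nuclei would overlap,
each pixel goes to the nucleus reached first, ties to the lower label id,
so zones partition cleanly. A cell is positive for a marker iff the marker
mask covers **at least 1%** of its scoring region (inclusive ">=",
the literal reading of the rule). Cytoplasmic TH is scored on the ring;
nuclear markers (FOXA2, SOX2) are scored on the nucleus pixel set itself,
consistent with their masks being restricted to nuclei — scoring a nuclear
marker on a cytoplasmic ring that the restricted mask can barely intersect
would be self-contradictory, so the generic perinuclear rule is applied
per localization, and both choices are configurable per marker.

Sections with fewer than `min_cells` (10) retained nuclei are flagged
low-quality: their per-cell fractions become `NA` (unstable denominators)
while pixel fractions are kept; the exclusion is logged.

Whether the "TH/FOXA2 double-positive signal" is a pixel-overlap fraction
or a double-positive cell fraction is genuinely ambiguous; both are
computed on every image (`th_foxa2_px_fraction`,
`th_foxa2_cell_fraction`), and the ANOVA runs on the pixel-signal variant
by default ("signal" wording), switchable in `pipeline_config()`.

## Statistics

Section-level feature values (fields averaged into sections — the unit of
replication is the organoid section, matching how the per-group ns are
counted) are tested by fixed-effects two-way ANOVA (genotype group x
differentiation day) with interaction. Because group sizes differ between
cells in practice, Type II sums of squares are used (on balanced designs
they coincide with the textbook sequential decomposition, which is how the
implementation is tested, to 1e-9). Pairwise group comparisons within each
day use the Tukey-Kramer HSD on estimated marginal means, which handles
unequal ns; adjusted p-values can never undercut the unadjusted ones, and
that invariant is asserted in the tests. Degenerate inputs are handled
explicitly: constant features are returned flagged without a test, empty
factor cells drop the interaction with a warning, single-level factors are
errors.

The clustergram view standardizes each feature (z-score) across the group
x day mean matrix and clusters both axes hierarchically with Euclidean
distance and average linkage — the conventional defaults of heatmap
clustergram tools; distance and linkage are exposed. Zero-variance
features are dropped with a message; an all-constant table is an error.
Features undefined for some sections (e.g. `links_per_node` when a section
has zero nodes) are excluded pairwise per feature, not listwise.

## The synthetic-section generator

The generator is the package's test bed and defines its study conditions.
One field contains `n_cells = 200` elliptical nuclei (semi-axis 8-12 px,
eccentricity 0.75-1, random orientation) placed on a jittered grid that
guarantees non-overlap (minimum center distance `2*rmax + gap/2`) and
rejects infeasible packings; 5% are pyknotic, drawn at the small end of
the radius range with a 2.0x intensity gain so that threshold separation
is possible by construction. Marker positivity is Bernoulli per cell at
the profile's `positive_fraction`, jittered per section (SD 0.03,
organoid-to-organoid variability). TH-positive cells (55% at baseline,
the mDAN-rich regime reported for such organoids) carry a thin
cytoplasmic rim and Poisson(1.2) primary neurites drawn as recursively
bifurcating polyline trees (segment length 8-14 px, bifurcation
probability 0.4, up to 2 generations, 3 px wide — wide enough to survive a
3x3 median filter); every drawn bifurcation and segment is logged as
ground-truth node/link counts. Channels are blurred with a Gaussian PSF
(sigma 1 px), overlaid with additive Gaussian noise (sigma 0.03), and
quantized to the 16-bit TIFF grid so in-memory and re-read images are
bit-identical. All randomness derives from the parameter seed;
identical parameters give identical output.

Two deliberately biological features of the generator matter for the
perinuclear rule. First, TH positivity is *spatially clustered* along a
random niche axis (noise SD 4% of the image size): organoid sections are
organized into neuron-rich and progenitor-rich territories rather than
salt-and-pepper mixtures, and with an "any overlap >= 1% of a ~200 px
ring" rule, a spatially random arrangement of branched TH+ cells would
mark nearly every neighboring cell positive — the rule is only meaningful
on niche-organized tissue, which is worth knowing when interpreting it on
real images. Second, neurites project into the neuron-rich side of that
axis, as neurites in tissue arborize within their own territory.

What the generator does **not** emulate: z-dependent optics, spectral
bleed-through, photobleaching, intensity gradients, nucleus shape
irregularity, touching/overlapping nuclei, or whole-organoid morphology.
Passing recovery tests therefore shows the pipeline is correct and
calibrated under controlled conditions — not that segmentation is robust
to every real-microscopy artifact.

## Calibration studies and problem sizes

The statistical studies run at desk scale, with sizes chosen to keep a
full validation run in minutes while preserving the study design:

* **Type-I error**: 500 null cohorts (4 groups x 3 days x 8 sections,
  ground-truth features without pixel rendering, isolating the test's
  calibration from segmentation noise); the genotype effect should be
  declared significant in 3-8% of cohorts at alpha = 0.05.
* **Power/specificity**: 50 repeats of the full image pipeline on cohorts
  of 20 sections per group x day (within the 20-40 sections per group of
  the motivating design), groups H vs P at days 10 and 35, fields of
  28 cells at 224 x 224 px. Patient-type deficits (TH fraction 0.55 to
  0.35, bifurcation probability 0.4 to 0.25, FOXA2 unchanged so the
  FOXA2+/TH- pool rises) are injected at day 35 only. Expected pattern:
  the H-P Tukey comparison non-significant at day 10 and significant at
  day 35 for all three headline features in at least 80% of repeats.
* **Recovery**: 20 sections at full generator defaults (~200 cells,
  512 x 512): per-section TH+ cell fraction within +-0.05 of truth and
  retained nucleus count within +-10% of the true viable count.

## Numerical choices and edge cases

* All strict-inequality size rules ("smaller than 100", "higher than
  10,000") are implemented strictly; boundary components of exactly 100 /
  10,000 px are kept, and this is pinned by tests.
* Thresholding uses ">" (mask strictly above threshold); the positivity
  rule uses ">=" ("at least 1%").
* An all-zero channel yields empty masks, not an error; non-finite pixels
  are rejected.
* Empty nuclei masks flag the image and its pixel fractions are `NA`.
* Coordinates in the R API are 1-based with matrices in (y, x) order, the
  native R convention.
* Per-image analysis is single-threaded and deterministic; re-running an
  identical configuration on identical inputs reproduces every output
  byte-for-byte.

## Known limitations

* Nuclei are non-overlapping by construction in the generator, so the
  watershed's behavior on heavily fused clumps is only exercised by the
  oversize-exclusion path.
* Node/link totals depend on the declared junction-merging and pruning
  settings; totals are comparable across images only under a fixed
  configuration.
* The per-image node count mixes soma-skeleton junctions with neurite
  bifurcations when somata are large; the validated recovery claim is for
  neurite masks, while section-level counts are validated as a monotone
  readout of injected branching.
* No per-neuron tracing, Sholl analysis, or mixed-effects modeling of
  cell line within genotype; features are per-image aggregates and the
  ANOVA treats sections as exchangeable within group x day.
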