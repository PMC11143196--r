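---
title: "Methods: single-cell spatial phenotyping of lymphoma tissue"
author: "spatlymph developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell spatial phenotyping of lymphoma tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatlymph)
```

## Scope and model

`spatlymph` implements the analysis stack used for single-cell spatial
phenotyping of highly multiplexed immunofluorescence (CODEX/PhenoCycler-style)
lymphoma tissue, specialized to the nodular lymphocyte-predominant Hodgkin
lymphoma (NLPHL) / T-cell-histiocyte-rich large B-cell lymphoma (THRLBCL)
spectrum. The pipeline stages are:

1. **Synthetic tissue** with full ground truth (`simulate_tissue`,
   `make_group_presets`) so every downstream stage is testable against known
   labels.
2. **Nuclear segmentation** (`detect_maxima`, `grow_regions`,
   `quantify_cells`, `compensate_spillover`): local-maxima seeding, fixed
   radius-bounded growth, a relative size cutoff, and neighbor spillover
   subtraction.
3. **Phenotype gating** (`default_schema`, `fit_marker_thresholds`,
   `assign_phenotypes`): deterministic marker co-expression rules replacing
   unsupervised clustering, with required and forbidden marker sets and
   most-specific-rule precedence.
4. **Abundance statistics** (`roi_composition`, `zscore_matrix`,
   `rank_sum_test`, `detection_rate`): per-ROI population fractions, pooled
   cross-ROI Z-scores, exact/approximate rank-sum tests, per-case
   detectability.
5. **Spatial statistics** (`build_neighbor_graph`, `interaction_scores`,
   `permutation_enrichment`, `voronoi_export`): 3–30 µm annulus neighbor
   pairs, size-corrected interaction scores, a within-ROI label-permutation
   null, and Voronoi maps.
6. **Morphometry** (`polygon_area_perimeter`, `tumor_nuclear_morphometry`,
   `positive_fraction`): shoelace-exact nuclear geometry and
   positive-cell-fraction quantification with per-case medians.

## The synthetic-tissue world

The generator's defaults *are* the stated modelling assumptions; they are
fixed once and are not tuned against test outcomes.

**Architecture.** Nodular presets (`group1`, `group2`) place 90% of cells
uniformly inside 4 nodule discs (radius 110 µm) in a 600 × 600 µm ROI with a
10% uniform background; diffuse presets (`group3`, `thrlbcl`) are homogeneous
Poisson. A hard minimum center-to-center spacing of 4 µm (about one
lymphocyte radius) is enforced by batch dart throwing; it removes degenerate
near-zero distances, consistent with the 3 µm lower bound of the interaction
annulus. Infeasible packings are rejected with an error rather than silently
relaxed.

**Composition.** Preset composition vectors are implementation choices
constrained only by the published qualitative gradients: tumor-B fraction
increases `group1 < group2 < group3 < thrlbcl`; TME-B decreases in the same
order; macrophage/monocyte content is maximal in THRLBCL (and the macrophage
fraction is strictly higher there than in any NLPHL preset); helper-T content
is highest in typical nodular disease. The published per-group Z-scores are
*data-dependent outputs* of the real cohort, not generative parameters, so
they are deliberately not matched numerically — only their orderings are.
Labels are drawn as an exact multinomial, so empirical fractions converge to
the configured composition at the binomial rate (tested at n = 10^4 within
3 SE).

**Rosettes.** The `group1` preset plants a TFH rosette around every tumor-B
(LP) cell: 4 TFH cells uniformly in a 5–12 µm annulus, drawn from the TFH
pool so composition is preserved. This is the generative counterpart of the
immunologic-synapse rosette, and it makes LP–TFH the strongest LP
interaction by construction — which is what the recovery tests assert.

**Intensities.** Each marker has a dim negative and a bright positive
log-normal component (meanlog log 12 vs log 400, sdlog 0.45 vs 0.35), the
usual right-skewed immunofluorescence shape; which component a cell draws
from is decided by its population's positive-marker set. The separation
(≈ 3.5 on the log scale) is wide enough that two-component gating recovers
the generating component for > 99% of cells; this is a *stated* property of
the synthetic world, so a green gating-recovery test certifies the gating
machinery, not robustness to heavily overlapping real-world stains. The spec
of this model is per-marker global rather than per-population-per-marker; a
per-population override adds expressive power no stated condition needs.

**Nuclear geometry.** Nuclei are star-shaped 14-gon "noisy ellipses" with
radii scaled so the expected polygon area equals the drawn area
(Normal(mean, sd) per population, floored at 4 µm²). Tumor-B mean areas per
preset are 30/40/60/50 µm² for group1/group2/group3/THRLBCL — encoding the
published ordering `group1 < group2 < THRLBCL < group3`; absolute values are
invented since none are published. Lymphocytes get 18 µm², macrophages
35 µm².

**What the generator does not model:** 3-D tissue, multicycle registration
artifacts, autofluorescence, FDC meshworks, segmentation errors upstream of
the cell table (unless you run the image path), and spatial intensity
gradients. Green tests therefore establish correctness of the statistics on
their stated inputs, not robustness to those artifacts.

**Scale.** Real ROIs in this setting average ~34,000 cells; defaults use
2,000 cells per ROI (and the heavier replicate tests 300–800) purely for
desk-scale runtimes. All statistics are size-agnostic.

## Segmentation conventions

The published description fixes "a radius of 5 and a size cut off factor of
0.1" without units or a reference quantity. Decisions taken here:

* **Radius** is 5 *pixels* of Euclidean growth around each seed, not an
  intensity-adaptive watershed — this mirrors the "radius for growth"
  semantics and keeps behavior parameter-predictable.
* **Size cutoff** is relative: regions with area below 0.1 × the median
  region area are dropped and labels recompacted.
* Seeds are strict maxima of the Gaussian-smoothed nuclear channel within
  the `maxima_min_distance` disc, above a fraction of the channel maximum;
  ordering is by descending intensity with row-major tie-breaks, and regions
  use 4-connectivity — all for determinism.
* A per-seed intensity floor (10% of the seed peak) stops discs from
  bleeding into background; pixels claimed by several seeds go to the
  nearest seed, ties to the brighter seed, then the lower label.
* **Spillover** adjacency is mask contact within a 1-pixel dilation
  (8-neighborhood); the correction
  `max(0, raw − alpha · mean(neighbor raw))` is computed simultaneously from
  uncorrected values, never iterated.

## Statistical conventions

* **Z-scores** are computed across *all ROIs pooled over groups* (that is
  the only scope under which per-population group values are comparable
  across columns of a summary table), then consolidated case-first
  (case = mean of its ROIs, group = mean of its cases). SD uses denominator
  n; zero-variance rows are emitted as zeros with a warning.
* **Rank-sum tests** use mid-ranks, exact enumeration of all
  `choose(n1+n2, n1)` labelings whenever `min(n1, n2) ≤ 10` (and the
  enumeration is small enough), otherwise the tie-corrected normal
  approximation with continuity correction. Two-sided p-values are
  `P(|W − µ| ≥ |W_obs − µ|)`. No multiple-testing correction is applied —
  raw p-values at the 0.05 level, matching the source analysis.
* **Detection** of a population in a case pools its ROIs and requires both a
  fraction floor (0.001) and a count floor (20); the floors are invented but
  fixed, and the detection *rates* reported by the acceptance script depend
  only on the encoded per-case outcomes, not on the floor values.
* **Interaction scores** operationalize "interaction count" as qualifying
  *pairs* (edges of the 3–30 µm annulus graph), which makes the published
  size correction well defined and symmetric: `S_ij = E_ij/(n_i + n_j)`,
  `S_ii = E_ii/(2 n_i)`. A per-cell partner-count matrix is exported
  alongside for comparison. Populations absent from an ROI are "not
  assessable" (`NA`), mirroring how such entries are reported.
* **The chance baseline** is label permutation with positions fixed,
  stratified by ROI — it conditions on the observed point pattern.
  Enrichment/depletion p-values use the add-one rule
  `(1 + #{S_perm ≥ S_obs})/(n_perm + 1)`, so they are never 0 and are
  uniform under the null (verified by KS test at 1000 replicates).
  Position-resampling (CSR) nulls are intentionally out of scope.
* **Voronoi maps** are computed exactly by half-plane clipping against the
  ROI rectangle (the independent `deldir` tessellation is used only as a
  test oracle). Collinear inputs are rejected.

## Numerical choices and degenerate inputs

arcsinh cofactor 150 (conventional, configurable); the two-component
threshold fit is deterministic (2-means min/max initialization + EM), so no
RNG is consumed; constant markers threshold above their maximum with a
warning rather than failing. Degenerate cases that *are* errors: empty cell
tables for rendering, empty ROIs/cores (named in the message), duplicate
cell ids in a graph, self-intersecting polygons, infeasible packings,
unknown groups/populations/stages. All randomness flows from a single seed
through a labeled stream derivation (`seed`, stage, ROI index), so partial
reruns reproduce.

## Known limitations

* Parquet and TIFF interfaces are not available offline in this build
  (no `arrow`/`tiff` runtime); CSV cell tables, CSV rasters and GeoJSON
  polygons are the supported formats, and `.parquet` paths fail with an
  informative error.
* The published interaction values come from a proprietary viewer whose
  exact ratio definition is only paraphrased; they are treated as ordering
  references, and no numeric interaction value is asserted.
* Gating thresholds are fitted, not transcribed — none are published.
* One published figure caption disagrees with the population table on the
  activated-cytotoxic definition (CD4 vs CD8); the table definition
  (CD3/CD8/LAG3/CD69) is implemented.

## A worked run

```{r demo, eval = FALSE}
cfg <- run_config(mode = "simulate", cases_per_group = 2, rois_per_case = 2,
                  n_cells = 800, seed = 1, outdir = "spatlymph_demo")
res <- run_pipeline(cfg)
res$zscores$group_z["macrophage", ]   # highest in thrlbcl
res$interactions$group1$S["tumor_b", "tfh"]
```

Every empirical claim above is recomputed by the test suite
(`tests/testthat/`, with `test-acceptance.R` holding the acceptance
criteria) or by `scripts/acceptance.R`; nothing in this vignette states a
result the code does not itself produce.
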