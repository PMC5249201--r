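---
title: "Micro-tile tissue density analysis: methods and design choices"
author: "pulmotile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-tile tissue density analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmotile)
```

## The measurement model

Histological scoring of pulmonary fibrosis (the Ashcroft scale and its
variants) is observer-dependent and usually sampled on a handful of
microscopy fields. `pulmotile` implements the alternative: an automated,
observer-independent density measurement over the *entire* lung section.

The section image is divided into a regular grid of square **micro-tiles**.
For tile $i$ the **pulmonary tissue density** is

$$ d_i = \frac{\text{tissue area inside tile } i}{\text{total tile area}} \in [0, 1]. $$

Densities are graded into 20 classes of width 0.05 (class $k$ covers
$[(k-1) \cdot 0.05,\; k \cdot 0.05)$, class 20 closed at 1), and the
per-class frequency $f_k$ is the share of included tiles in class $k$.
Two indexes summarise a section:

* $D_m = \frac{1}{n}\sum_i d_i$, the **mean tissue density** — sensitive to
  any morphological change, including diffuse septal thickening;
* $\mathrm{HDF}_m = \sum_{k \ge c} f_k$, the **high tissue density
  frequency** — the share of tiles at densities that lesion-free
  parenchyma essentially never produces, hence a fibrosis-specific index.

The threshold class $c$ is not a constant: it is **calibrated from the
saline-control group** as the smallest class such that every class at or
above it has a mean control frequency below a cutoff (1% by default), and
the supra-threshold range is required to be contiguous up to class 20. On
sections simulated at the package defaults this calibration typically lands
at class 11–12, i.e. HDFm counts tiles with $d \gtrsim 0.55$.

Analysis proceeds at a fixed physical pitch of 3.632 µm/pixel. Native
high-magnification scans are segmented first and then **block-averaged**
(factor 8 for an x20 → x2.5 reduction; the synthetic generator uses 4 from
a 0.908 µm native pitch), so each analysis pixel is itself a tissue
fraction and no tissue mass is lost to thresholding at coarse resolution.

## Segmentation

The tissue/background decision is luminance thresholding: Masson-trichrome
tissue (collagen blue, cytoplasm red/purple) is saturated and dark against
a near-white slide, so a pixel is tissue iff its Rec. 601 luma
$0.299R + 0.587G + 0.114B$ falls below a threshold; Otsu's method on
non-sentinel pixels is the automatic default, a fixed threshold the
override. Pixels within `white_sentinel_tolerance` (default 2) of pure
white are treated as **manually erased**: the workflow this package
automates deletes bronchi and vessels (diameter > 200 µm) by painting them
white in an editor, and those regions must count as neither tissue nor
background. Exclusion can equivalently be supplied as a separate mask
file; both routes feed the same inclusion logic
(`inclusion = footprint AND NOT exclusion`).

Two segmentation modes exist because source material varies:

* `binary_native` (preferred): hard threshold at the native pitch, then
  block reduction to fractional analysis pixels;
* `soft_analysis`: when only reduced images exist, a linear luminance ramp
  $\mathrm{clamp}((T - L)/T, 0, 1)$ approximates the per-pixel tissue
  fraction directly.

The footprint (where tiles are laid at all) is the tissue mask after
morphological closing (disk radius 10 px at analysis pitch ≈ 36 µm, sized
to bridge alveolar lumens of 50–100 µm), filling of interior holes below
5000 px, and removal of connected components below 0.1% of the image area
(debris floor).

## Tile geometry

Tiles are anchored at the image origin; trailing partial tiles are
excluded rather than renormalised, so the denominator of $d$ is always the
full tile area, and a tile is included only when at least `min_inclusion`
(default: all) of its pixels lie in the inclusion domain.

The default tile side is **10 analysis pixels = 36.3 µm** (tile area
1319 µm²). This is a deliberate design choice between two readings of the
field's customary "30–56 µm²" micro-tile figure: read as an *area* it
implies ~7 µm tiles, read as a *side length* it implies 30–56 µm tiles.
Seven-micrometre tiles are smaller than an alveolar septum is thick, so on
lesion-free parenchyma they produce a bimodal density distribution (a tile
is either inside a septum, $d \approx 1$, or in a lumen, $d \approx 0$)
with several percent of tiles in the top class — under which the
control-calibration rule ("every supra-threshold class below 1%") can
never be satisfied, while it demonstrably is satisfied in practice at a
threshold near class 12. Tiles a few tens of micrometres wide average over
roughly one alveolus, giving the unimodal low-density control distribution
with a thin upper tail that the calibration rule presumes. Hence the side
reading is the default; `tile_side_px` is a free parameter and the area
reading (`tile_side_px = 2`) remains available.

## The synthetic generator

No deposited slide scans exist for this kind of study, so the package
ships a generator that emulates the morphology the pipeline measures —
it is the test bed for every stage:

* **Septal network.** A Gaussian random field smoothed at
  $\sigma = \text{alveole scale}/\pi$ has zero-contour spacing close to the
  alveole scale; septa are the uniform-thickness band
  $|F|/|\nabla F| < \tau$ around those contours, with $\tau$ set by
  quantile so the areal tissue fraction hits `baseline_septal_fraction`
  exactly (default 0.25, a realistic parenchymal areal fraction). At the
  defaults (alveole scale 40 µm, mouse-sized lumens) septa come out
  ~10 µm thick.
* **Fibrotic foci.** Random discs (characteristic radius 80 µm, jittered
  ×0.7–1.3) are accumulated until a target fraction of the non-excluded
  area is covered; inside a focus, pixels are tissue with probability
  `lesion_density` (default 0.9), emulating dense collagen with residual
  airspace. Achieved coverage overshoots the target by at most one disc.
* **Vessels.** Rings of outer diameter 250 µm (above the 200 µm exclusion
  criterion) drawn as tissue and recorded, with a 10 µm margin, in the
  exclusion mask.
* **Rendering.** Tissue classes are painted in Masson-like hues
  (purple-red septa, blue-shifted lesions, darker vessel walls) on a
  near-white background with Gaussian channel noise (sd 8). Optics blur,
  staining gradients, folds and debris are *not* modelled — segmentation
  on these images is easier than on real slides, so pipeline-recovery
  tests validate the arithmetic chain, not real-world segmentation
  robustness.
* **Study design.** `simulate_study` mirrors the canonical bleomycin
  dose-response design: 6 saline controls and 12 animals per dose at 0.25,
  0.5, 0.75 and 1 mg/kg, with lesion coverage $0.16 \cdot \text{dose}^{0.6}$
  — chosen so that control $D_m \approx 0.25$ rises by roughly 20–40%
  at the top dose, the regime such studies report. Covariates (Ashcroft
  score 0–8, micro-CT HU peak, dynamic compliance, FVC, weights) are
  saturating logistic functions of each animal's achieved coverage plus
  Gaussian noise, with noise scales set so correlations with the density
  indexes land in the $|r| \approx 0.85$–0.95 range — strong but not
  degenerate. The Ashcroft link saturates, as the real scale's ceiling at
  8 does.

All randomness descends from one master seed; per-animal seeds are
`master_seed * 1000 + animal index`, and covariate noise uses offset 999,
so studies are bit-reproducible and animals are independently perturbed.

By default `simulate_study` takes each animal's densities from the
ground-truth tissue mask (the generator's own definition of truth, and an
order of magnitude faster); `quantify = "pipeline"` instead renders every
section and runs the full segmentation route. Image-route recovery of
truth $D_m$ (within ±0.03) is exercised separately on single sections, so
the study-level default does not hide a pipeline defect.

## Statistics layer

Group comparisons follow the field's convention: one-way ANOVA with
Dunnett's test against control (multivariate-t critical values, via
`multcomp`) for continuous readouts, Kruskal–Wallis with Dunn's rank
contrasts for ordinal ones (Ashcroft scores default nonparametric). Dunn's
contrasts are Bonferroni-adjusted over the control comparisons only — the
only contrasts the design interprets. Correlations report the Spearman
coefficient with a tie-corrected asymptotic p-value plus the OLS line
(slope/intercept and its own p) for plotting, since both the rank and the
linear analysis are customarily shown together. Zero-variance readouts
give p = 1 with a warning rather than an error, so a fully null study
still produces a complete results table.

## Numerical choices

* Class boundaries are lower-inclusive; a $10^{-9}$ guard inside the
  grading keeps exact rational boundary densities (e.g. $60/100 = 0.6$) in
  the class they open despite IEEE division error.
* Block reduction averages trailing partial blocks over their true pixel
  count (no zero padding), so border tissue is not diluted; with evenly
  dividing dimensions the global tissue mean is conserved exactly.
* Partial border *tiles* are dropped, keeping the density denominator
  exact; grid anchoring is deterministic at the origin, so no tie-breaking
  is needed anywhere.
* $|D_m - \sum_k f_k m_k| \le 0.025$ (half a class width, $m_k$ the class
  midpoint) holds for any section and is asserted in the tests as the
  consistency link between the two summaries.
* Degenerate inputs fail loudly: empty tissue rasters, sections with no
  included tile, and calibrations where even class 20 exceeds the cutoff
  raise errors naming the condition.

## Problem sizes

The shipped tests and the acceptance script run on sections of 400–1200 µm
at the native 0.908 µm pitch and on studies of up to 54 animals; these
sizes give tile counts (hundreds to tens of thousands per section) at
which every group-level property the package claims is measurable with
comfortable margin. Whole mouse lung sections (~10 × 8 mm) are simply
larger instances of the same arithmetic; memory scales with the native
pixel count (~10⁸ pixels ≈ a few GB at double precision).

## Known limitations

* Segmentation is luminance-only; it does not deconvolve Masson stain
  components, and heavy erythrocyte contamination or pale collagen would
  shift the Otsu threshold. Real-slide validation requires real slides.
* Bronchi/vessel exclusion is consumed, not computed: masks (or
  white-painted regions) are inputs, as in the manual workflow.
* The generator's lesions are isotropic discs; real fibrotic foci are
  irregular and often subpleural. Covariates are generated from lesion
  burden, so their correlations validate directionality and the statistics
  layer, not biology.
* HDFm depends on the calibrated threshold class; comparing HDFm across
  studies requires calibrating on each study's own control group, exactly
  as implemented.
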