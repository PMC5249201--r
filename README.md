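# pulmotile

Automated, observer-independent quantification of pulmonary fibrosis from
stained whole lung section images.

Histological scoring of lung fibrosis (Ashcroft-style grading) is
observer-dependent and samples only a few microscopy fields. `pulmotile`
implements the automated alternative: it measures **pulmonary tissue
density** in thousands of micro-tiles crisscrossing the alveolar parenchyma
of an entire section, and condenses the result into two indexes.

For micro-tile *i*, density is the area ratio

    d_i = tissue area inside tile i / total tile area,  d_i in [0, 1]

Densities are graded into 20 classes of width 0.05, with per-class
frequencies `f_k`. The indexes are

* **Dm** = mean of `d_i` over all included tiles — the global index of
  morphological change;
* **HDFm** = `sum(f_k, k >= c)` — the *high tissue density frequency*, a
  fibrosis-specific index counting tiles at densities that healthy
  parenchyma essentially never reaches. The threshold class `c` is
  calibrated from the saline-control group: the smallest class such that
  every class at or above it holds less than 1% of control tiles.

Around this core the package provides: PNG/TIFF section I/O with physical
pixel pitch, luminance (Otsu) tissue segmentation with white-sentinel
handling of manually erased bronchi/vessels, block-average reduction from
scan to analysis resolution (3.632 µm/pixel), footprint/exclusion logic,
pseudocolor 2D density reconstructions (light blue → yellow over the 20
classes), a statistics layer (ANOVA + Dunnett, Kruskal–Wallis + Dunn,
Spearman correlations, percent-change summaries), and a synthetic
lung-section generator with ground truth so the whole pipeline is testable
without slide scans.

## Worked example

Simulate a fibrotic section (12% lesion coverage), quantify it from the
rendered image, calibrate the HDFm threshold on six lesion-free control
sections, and compare:

```r
library(pulmotile)

sec <- simulate_section(section_params(lesion_coverage = 0.12, seed = 42))
sec
#> synthetic_section "synthetic-42": 1322 x 1322 native px, lesion coverage 0.121
#>   (target 0.120), truth Dm 0.331

q <- quantify_section(sec$image, exclusion = sec$exclusion, reduce_factor = 4L)
q
#> section_quantification "synthetic-42": 970 tiles, Dm = 0.3313
#>   (segmentation threshold 175.8)

controls <- lapply(1:6, function(i)
  density_histogram(simulate_section(section_params(seed = i),
                                     render_rgb = FALSE)$truth_map))
cal <- calibrate_threshold(controls, cutoff = 0.01)
cal
#> calibration_result: threshold class 12 (cutoff 0.01;
#>   max supra-threshold control frequency 0.002387)

hdf(q$hist, cal$threshold_class)                       # 0.1278
mean(sapply(controls, hdf, cal$threshold_class))       # 0.0032
```

Reading the numbers: the image-route Dm (0.3313) recovers the ground-truth
Dm (0.331) of the simulated section; calibration lands at class 12, i.e.
HDFm counts tiles with density ≥ 0.55; and the lesioned section's HDFm
(0.128 ≈ its lesion coverage) stands forty-fold above the control mean
(0.003) while Dm rose only ~30% — HDFm is the sharper discriminator of
focal fibrosis, which is the point of the index.

A full dose-response study (one saline control group plus four dose groups
with monotone lesion burden, per-animal covariates) is one call:

```r
st <- simulate_study(study_params(master_seed = 1))
st$table                                  # 54 animals: Dm, HDFm, covariates
dose_response(st$table, "Dm")             # ANOVA + Dunnett vs control
correlate(st$table, "HDFm", "ashcroft_score")   # Spearman r + OLS line
```

A command-line front end (`inst/cli/pulmotile.R`) exposes the same
pipeline as `simulate`, `quantify`, `calibrate`, `reconstruct` and `stats`
subcommands; see the header of that script for usage.

## Method details

The methods vignette (`vignettes/pulmotile-methods.Rmd`) documents the
measurement model, the tile-geometry and calibration design choices, what
the synthetic generator does and does not emulate, and known limitations.
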