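---
title: "Methods: hyperspectral rice yield classification and the lodging index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral rice yield classification and the lodging index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperice)
```

## The problem

Regional rice trials score breeding lines into yield classes by destructive
harvest: class A above 750 kg per mu, class B between 700 and 750, class C
below 700 (one mu is about 667 m²). `hyperice` implements a non-destructive
alternative built on UAV hyperspectral imagery of a trial in which 13
japonica lines are planted in triplicate on a 3-row × 13-cell grid, each row
holding one replicate of every line in a reshuffled order. A 176-band camera
spanning 400–1000 nm records canopy reflectance; a per-line *lodging index*
(the count of field replicates in which the line lodged, 0–3) enters as a
single extra feature. The package's central question is the one this design
isolates: how much of the classifier's ability to recognise high-yield
(class A) lines comes from spectra, and how much from lodging.

## Pipeline and models

**Calibration.** Raw counts are converted to reflectance with the standard
white/dark frame formula
$\rho = \rho_\mathrm{panel}\,(x - d)/(w - d)$ per band, with
$\rho_\mathrm{panel} = 0.34$ (the white panel's preset reflectance). Values
are clipped to $[0,1]$; counts above the white level are treated as
saturation. The synthetic sensor is affine
($x = g_b\,\rho + d_b$ with band-wise gain), so on simulated scenes the
calibration inverts the sensor exactly (the tests require $<10^{-9}$
before clipping).

**Background removal.** Each pixel's spectral angle
$\theta(x, r) = \arccos\big(\langle x, r\rangle / \lVert x\rVert\,\lVert
r\rVert\big)$ is computed against the mean rice and mean soil spectra of a
reference library; a pixel is background iff its angle to soil is no larger
than its angle to rice. Ties go to background — contaminating the rice
sample set with soil is the costlier error. The angle is invariant to
positive scaling, which is the point: illumination differences rescale
spectra without changing their direction.

**ROIs and sampling.** Plot rectangles are shrunk by a 2-pixel margin (the
field protocol removes edge rows where neighbouring plots mix; no width is
standard, 2 px is the package default) and intersected with the rice mask.
From each ROI, 300 pixels (the trial's sampling depth) are drawn uniformly
without replacement, excluding zero-valued (removed) spectra. Whether the
original protocol stratified spatially is unknowable from its description;
uniform sampling is implemented, and stratification is deliberately left
out rather than guessed.

**Dimension reduction.** Adjacent narrow bands are highly redundant.
`band_correlation_matrix()` reports, per band, the longest contiguous run of
bands correlating above 0.9 with it; with runs of roughly 8–10 bands the
default aggregation averages non-overlapping groups of $g = 8$ consecutive
bands, turning 176 bands into 22 channels. $g$ is a parameter — the run
diagnostic justifies the default but does not auto-tune it, because a single
global $g$ is what the trial protocol used. A PCA route (`pca_reduce()`,
22 components by default) is provided for comparison; remainders when $g$
does not divide the band count form a final short group.

**Vegetation indices.** A registry of 41 literature indices (NDVI, GNDVI,
SAVI, EVI, PSRI, MTCI, ARI, REIP, …) is evaluated per pixel on the
full-resolution spectrum, each index declared as wavelength anchors plus a
rational formula (`+ - * /` only), so the registry round-trips through JSON
and can be replaced wholesale when a different roster is needed. Anchors
resolve to the nearest band center; an anchor outside 400–1000 nm is an
error, a zero denominator flags that sample's index as undefined. Indices
are computed per pixel *before* band aggregation — aggregation would shift
anchor reflectances by averaging across 3.4 nm-spaced neighbours.

**Fusion and labels.** The fused table has 22 channels + 41 indices
(+ lodging index when enabled: 64 vs 63 feature columns), one row per
sampled pixel, labelled by its line's yield class. Boundary yields go to
class B (750 and 700 are both "between"); class A requires strictly more
than 750. Texture maps (local range and standard deviation over 3×3
windows, local entropy over 9×9, reflective padding) are available but
excluded from the default table: in the source trial they did not improve
classification.

**Evaluation designs.** *Intraline*: hold out one replicate of every line —
generalisation across field position; all three leave-one-replicate-out
plans are enumerated rather than picking one at random, which supersets the
single random split of the original protocol and is deterministic.
*Interline*: hold out one whole line per class, train on the remaining ten
lines — generalisation to unseen cultivars; with class sizes 2/7/4 the
Cartesian product gives 2 × 7 × 4 = 56 plans, all enumerated.

**Classifier.** Gradient-boosted trees (xgboost) with the multiclass
softmax objective; the boosted-tree objective's regularisers — γ per leaf
and λ on squared leaf weights — are part of the default grid
(depth {3, 5, 7} × η {0.05, 0.1, 0.3} × trees {100, 300} × γ {0, 1} ×
λ {1, 10}). Grid search is by 3-fold stratified cross-validation on
training plots only (the original protocol states grid search but no
selection protocol; stratified 3-fold with a fixed seed is the package's
choice), ties broken by grid order, then a refit on the full training set.
Baselines (linear and RBF SVM, random forest, naive Bayes, LDA) are
delegated to e1071, randomForest and MASS; AdaBoost is a compact in-package
multiclass SAMME over shallow CART trees. Metrics are pixel-level 3×3
confusion matrices with per-class precision and recall (precision defined
as 0 for an empty predicted column); plot-level aggregation is possible by
majority vote over a plot's pixels but pixel level is canonical here.

## What the synthetic generator emulates

No imagery from the trial is deposited, so `simulate_field()` generates
scenes carrying exactly the statistical structure the analysis assumes:

- **Geometry.** A `n_replicates` × `n_lines` cell grid (default 3 × 13,
  hence 39 plots), each plot a 24 px square of rice inside a soil border,
  line order permuted per row.
- **Spectra.** Rice canopy: low visible reflectance with a green bump, a
  red-edge rise near 700 nm, a NIR plateau near 0.5. Stem: brighter
  visible, flatter NIR. Soil: a gentle monotone slope. These reproduce the
  qualitative rice/soil separation without claiming radiative-transfer
  realism.
- **Within-plot noise.** Independent Gaussian noise per band
  (`noise_sd = 0.025`), so each band inside a plot is exactly normally
  distributed — the distributional shape observed for real per-band pixel
  histograms, and the reason a normality check on simulated plots passes by
  construction.
- **Between-line variation.** Each line scales the canopy curve by a
  factor with sd `line_scale_sd = 0.012`, and each plot by a further
  `plot_scale_sd = 0.005` (replicate-to-replicate growth differences). The
  noise level deliberately *dominates* the line differences: in the source
  trial the mean curves of different lines were nearly indistinguishable
  while single-pixel spectra spread widely, and an unseen line must not be
  identifiable from brightness alone.
- **Class structure.** Class A adds a small flat offset (0.006) — smaller
  than the line-to-line spread, so an unseen A line is *not* reliably
  recognisable from spectra, mirroring the weak interline class-A
  performance observed without lodging. Classes B and C sit at ±0.006 on a
  pigment-like Gaussian bump centred at 620 nm, a direction orthogonal to
  overall brightness: B/C spectra carry genuine but noisy class signal
  (their per-pixel separation is far from perfect), while class A sits
  midway on this axis and remains spectrally ambiguous. Without some B/C
  signal, spectra would be pure noise beyond class A and no fused model
  could beat the lodging-only baseline even in principle.
- **Lodging.** A lodged plot's spectrum is the convex combination
  `(1 − α)·canopy + α·stem` with `α = 0.4` — the mixing weight is a free
  parameter of the generator, as no quantitative lodging perturbation is
  documented for the trial. The default lodging profile assigns both class
  A lines index 1 (one lodged replicate) and spreads B/C lines over
  {0, 2, 3}: index 1 uniquely marks class A, but lodging cannot separate B
  from C. Under this profile a lodging-only classifier's intraline accuracy
  is 9/13 ≈ 69.2% by construction.
- **Sensor.** Band-wise affine gain/dark frames consistent with the 34%
  panel, so calibration is exactly invertible — closed-loop testability.

All randomness flows from one seed through derived child streams;
simulation is bit-reproducible.

What the generator does **not** emulate: lens distortion (the real
workflow applies a vendor correction file; simulated scenes are
distortion-free), atmospheric and illumination drift between flights,
orthomosaicking, spatially correlated noise, weeds, and growth-stage
differences. Passing tests therefore demonstrate that the *pipeline*
recovers known structure — not that the spectral–yield association holds in
any particular field.

## The replicated ablation study

`lodging_ablation_study()` repeats the full pipeline over seeds and
reports, per seed: interline class-A precision/recall with and without the
lodging index (averaged over a per-seed random subset of interline plans),
and intraline accuracy of the fused model vs the lodging index alone
(training on replicates 1–2, testing on replicate 3 — the design under
which the lodging-only baselines are defined). Three orderings are the
study's substance:

1. with the lodging index, unseen class-A lines are recovered perfectly
   (precision = recall = 1) in ≥ 90% of seeds;
2. removing the index strictly lowers class-A precision on average;
3. the lodging index alone underperforms the fused model on average.

**Problem sizes.** The study defaults to 60 sampled pixels per plot, 6
interline plans per seed and a single fixed grid point (depth 4, η 0.3, 60
trees, γ 0, λ 1) for every condition — the same parameter space for the
paired with/without runs, so the comparison is not confounded by model
selection. These sizes are the package's choice for a replicated,
desk-scale study; the full 300-pixel, 56-plan, grid-searched analysis is
available by passing the corresponding arguments. The acceptance script
runs 10 seeds; the test suite runs 20.

## Numerical choices and degenerate inputs

- Calibration requires `white > dark` at every band; equality is an error.
- The spectral angle of a zero vector is undefined and raises an error;
  SAM treats all-zero pixels as background.
- SAM ties (angle to soil equal to angle to rice) go to background.
- An ROI emptied by the margin, or containing no rice pixels, is an error
  naming the plot; a sampling request exceeding the eligible pixel count
  reports the deficit.
- Zero-variance bands are excluded from correlation runs and reported.
- Pixel coordinates are 0-based `(row, col)`; rectangles are half-open.
- Grid-search ties take the first grid row, making selection deterministic.
- LDA drops features with zero pooled within-class variance (e.g. the
  lodging index on degenerate layouts) rather than failing.
- Yield-class boundaries: 750 → B, 700 → B; negative yields are errors.

## Known limitations

- Endmember curves are stylised; absolute index values (EVI, MTCI, …) on
  synthetic scenes should not be compared with field studies.
- The lodging mixing weight and class offsets are generator conventions,
  not measured quantities; only orderings and recovery properties — not
  absolute accuracies — are meaningful summaries of synthetic runs.
- Replicates of a line share one endmember, so intraline spectral
  memorisation is easier than in a real field, where replicate-to-replicate
  variation is larger and position-dependent.
- The pipeline classifies; it does not regress yield, detect lodging from
  imagery, or process point clouds.

```{r example, eval = FALSE}
sim <- simulate_field(sim_config(), seed = 1)
features <- extract_features(sim, n_samples = 60, seed = 1)
plans <- make_interline_splits(sim$fieldmap)
model <- train_classifier(features, plans[[1]],
                          model_config(grid = default_grid("xgboost")))
evaluate(model, features, plans[[1]])
```
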