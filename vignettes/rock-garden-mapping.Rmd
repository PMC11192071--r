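---
title: "Mapping rock gardens and modelling the population they could feed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping rock gardens and modelling the population they could feed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mulchmap)
```

## The problem

Pre-contact farmers on Rapa Nui (Easter Island) improved their nutrient-poor
volcanic soils by *lithic mulching*: spreading and mixing broken rock into
cultivation plots ("rock gardens") to retain moisture and release mineral
nutrients. How much of the island was gardened this way matters well beyond
agronomy — rock-garden area is the key input to carrying-capacity models
that anchor the long-running debate over the island's pre-European
population size.

`mulchmap` implements the full analysis chain for this question:

1. **Scene simulation** — paired VNIR (1.2 m) and SWIR (3.7 m)
   multispectral rasters with known ground truth;
2. **Supervised classification** — Gaussian maximum likelihood (MLC),
   maximum entropy (MaxEnt), and a bootstrapped decision-tree ensemble
   (RF), with an 80/20 polygon-level training protocol;
3. **Pan-sharpening** — PCA component substitution of SWIR to VNIR
   resolution, plus band stacking;
4. **Accuracy assessment** — confusion matrices, recall/precision/F1,
   overall accuracy, Cohen's kappa, TPR/TNR;
5. **Garden products** — polygonization, a 10 m² minimum-mapping-unit
   filter, exclusion masks, and a 500 m kernel-density surface;
6. **Carrying capacity** — conversion of garden hectares into supported
   population under six cultivation scenarios, and a diet-adjusted
   summary.

Commercial satellite imagery and field training polygons cannot be
redistributed, so the package is built around a synthetic-scene generator
whose statistical structure encodes the one premise the analysis rests on:
**mulch is separable from its look-alikes in SWIR, and not in VNIR.** All
claims about real imagery remain qualitative; the tests establish relative
(SWIR vs VNIR) behaviour, never the published absolute accuracies.

## The spectral model

Each land-cover class (bare soil, bedrock/colluvium, forest/trees, grass,
mulch, urban/developed) is a 16-band multivariate Gaussian with
compound-symmetric covariance
$\Sigma_c = \sigma_c^2\,[(1-\rho)I + \rho J]$, $\rho = 0.3$ by default.
Compound symmetry is the simplest positive-definite structure with a
controllable Mahalanobis geometry: a mean shift along the all-ones
direction is damped by the shared correlation, while a shift in a band
*pattern* orthogonal to it is not.

The default library exploits exactly that. Mulch carries the same VNIR
signature as bedrock/colluvium up to a 2-DN offset (Mahalanobis distance
0.42, far inside the noise), but an oscillating SWIR signature — alternating
high-reflectance and absorption bands, the caricature of fresh mineral
surfaces and retained moisture — at Mahalanobis distance ≥ 7 from every
other class:

```{r mahal}
lib <- default_spectral_library()
round(c(
  swir_mulch_bedrock = mahalanobis_separation(lib, "mulch",
    "bedrock_colluvium", band_names("swir")),
  vnir_mulch_bedrock = mahalanobis_separation(lib, "mulch",
    "bedrock_colluvium", band_names("vnir"))), 2)
```

Placing mulch's SWIR separation in a pattern rather than in overall
brightness has a second purpose: the per-pixel VNIR mean stays a good
surrogate for the first SWIR principal component, which keeps PCA
pan-sharpening spectrally consistent (see below). Reflectances are 8-bit
range floats (0–255), clipped — not wrapped — at the bounds, mirroring the
8-bit delivery format of the imagery this emulates.

## The synthetic scene

`generate_scene()` places seeded elliptical patches with jittered
boundaries on a grass background (grass being the dominant natural cover),
then draws each pixel's spectrum from its class model: SWIR bands on the
coarse grid, VNIR bands on the fine grid with the truth upsampled by
nearest neighbour. Mulch patch centres are biased toward the high-x map
edge (`coastal_bias`), giving density surfaces the coastal clustering that
the island-wide mapping shows; the tests for density maxima depend on this
structure.

Defaults: a 120 × 120 SWIR grid (444 m square, a 370 × 370 VNIR grid)
with cover fractions bare soil 0.10, bedrock 0.12, forest 0.15, mulch
0.05, urban 0.04. These sizes keep one full replicated experiment (20
scenes × 3 classifiers × 2 band sets) in the low minutes on a single CPU;
they are desk-scale stand-ins for an island two orders of magnitude
larger, chosen once as the package's study condition.

Training polygons follow the field survey's design: 224 features split
27/66/25/36/40/30 across the six classes, with per-class areas in the
survey's proportions (0.101/0.090/0.235/0.090/0.031/0.053 km²). The
absolute areas are rescaled so training covers ~12% of the scene —
island-absolute areas would leave a desk-scale scene with almost no
training pixels. Polygons are cell-aligned rectangles placed wholly inside
single-class regions, so the centre-containment rasterization rule
recovers them exactly.

What the generator does **not** emulate: spatial autocorrelation of
spectra within a class (pixels are conditionally independent),
illumination and terrain effects, mixed pixels at patch boundaries, cloud
artifacts beyond user-supplied mask polygons. Consequently a passing test
suite shows the *machinery* is correct and the *relative* SWIR/VNIR
conclusion follows from the spectral premise — it does not certify
real-imagery accuracy values.

## Classifiers and the training protocol

All three classifiers are native implementations behind one interface
(`fit_*`/`predict_*`/`classify_matrix_*`):

* **MLC** — per-class mean and covariance (sample statistics), Bayes
  discriminant $g_c(x) = \ln\pi_c - \tfrac12\ln|\Sigma_c| -
  \tfrac12(x-\mu_c)^\top\Sigma_c^{-1}(x-\mu_c)$, uniform priors by default
  (class-frequency priors selectable), ridge $10^{-6}\times$ mean diagonal
  for invertibility. The vectorized path is tested to $10^{-10}$ against a
  per-pixel brute-force oracle.
* **MaxEnt** — L2-penalized multinomial logistic regression on per-band
  z-scored linear features, fitted by damped Newton iteration to a
  $10^{-8}$ gradient max-norm. Linear features are the minimal
  maximum-entropy model; the species-distribution tool originally used for
  this task derives richer feature transforms that are not reconstructable
  from its description, so hinge/quadratic features are deliberately out
  of scope. The penalty covers the intercepts too, so the large-λ limit is
  the uniform distribution — the "no information" reading of maximum
  entropy; the fitted optimum is verified against finite-difference
  gradients.
* **RF** — CART trees (Gini impurity, axis-aligned splits, midpoint
  thresholds), each on a bootstrap resample with `floor(sqrt(p))` features
  per node, majority vote. Compiled (Rcpp) with a self-contained RNG so a
  seed fully determines the forest.

One hyperparameter setting per model (the defaults above) is used
throughout — the "tune length 1" protocol: tuning grids were reported not
to change the published ranking, so none are searched here.

The 80/20 split assigns **whole polygons**, not pixels, per class
(`split_train_val()`), preventing spatially adjacent samples of one
polygon from leaking across the split; a pixel-level split is available
behind `unit = "pixel"` for fidelity experiments. The replication harness
(`compare_band_performance()`) caps training sets at 4 000 pixels per fit
(seeded subsample) to bound forest training time; validation pixels are
never subsampled.

Ties everywhere — argmax over discriminants, probabilities, or votes —
break toward the lowest class index in the canonical class order.

## Pan-sharpening

`pansharpen_pca()` follows the component-substitution recipe:
cubic-resample SWIR to the VNIR grid (Keys kernel, $a=-0.5$, the standard
"cubic convolution" of imagery pipelines), PCA across the 8 bands,
affine-match the VNIR-mean intensity to PC1 (mean/variance matching,
sign-aligned; full CDF matching adds nothing at these scales), substitute,
invert. No true panchromatic band enters the pipeline, so the VNIR band
mean is the intensity surrogate. If PC1 has zero variance the input is
spatially constant and the resampled raster is returned unchanged.

Spectral consistency is the design criterion: block-averaging the
sharpened product back to 3.7 m correlates ≥ 0.95 per band with the
original SWIR on default scenes. This is the property the tests pin down;
it is what makes the sharpened product safe to classify.

## Accuracy assessment

`confusion_matrix()` keeps unclassified predictions in a dedicated column;
they count as errors unless explicitly dropped. `classification_metrics()`
reports per-class recall/precision/F1/TNR, their unweighted macro
averages, overall accuracy and Cohen's kappa. Published tables for this
problem print a single recall/precision/F1 per model without stating the
averaging rule, so both the macro averages and the mulch-class values are
exposed — either interpretation is checkable. Zero-denominator ratios are
reported as 0 with an `undefined` flag, never as `NaN`, keeping aggregate
math total and auditable. The shipped reference tables
(`reference_accuracy_metrics()`) satisfy F1 = harmonic mean(precision,
recall) to ±0.001 on every row — an internal-consistency regression test
on the published constants.

## Garden products

`polygonize()` turns connected components of predicted mulch into garden
polygons (4-connectivity by default, matching standard GIS raster-to-
polygon behaviour; 8-connectivity behind a flag), with area = cell count ×
pixel area. The cleaning that was originally a ~2-hour manual pass is
replaced by two rule-based steps, applied in the fixed order polygonize →
mask → minimum area (the original order is unstated; fixing it makes runs
reproducible):

* `apply_exclusion_mask()` drops polygons whose **centroid** lies inside a
  mask polygon (urban areas, clouds). Centroid membership is deterministic
  and cheap; geometric intersection is out of scope. Masks are inputs,
  never derived — deciding what counts as "disturbed" is field knowledge.
* `filter_min_area()` removes polygons strictly below 10 m². One 3.7 m
  pixel is 13.69 m², so on pure SWIR products the filter is a no-op; it
  bites on pan-sharpened 1.2 m products (1.44 m²/cell), which is where the
  single-pixel conversion artifacts it targets arise.

`kernel_density()` offers two summaries on a 500 m lattice: `cellsum`
(default) apportions polygon area to the cell holding its centroid —
parameter-free and exactly conservative — and `quartic` evaluates an
area-weighted quartic kernel with h = 500 m, for a smoother surface. The
published method names only a cell size, not a kernel, which is why the
conservative mode is the default.

## Carrying capacity

The demographic model is deliberately plain arithmetic, applied to printed
constants: a ton-per-year of sweet potato yields 2 809 kcal/day; a person
needs at most 2 785 kcal/day; published per-hectare yields cover three
cultivation frequencies × two nitrogen levels. Then for garden area $A$
(ha), duty-cycle fraction $f$, and yield $y$:

$$\text{people} = \left\lfloor \frac{A \cdot f \cdot y \cdot 2809}{2785} \right\rfloor$$

Three choices reproduce the published twelve-row table exactly and are
worth recording:

* **The 15-off/3-on land fraction is 1/6** (duty cycle
  years-on/years-total), not the "25%" a table caption states: 1/6
  reproduces the printed areas (3 133.9 → 522.3 ha; 760 → 126.67 ha) and
  25% does not. The caption figure stays available via
  `fifteen_three = "quarter"`.
* **Populations use floor division**, not rounding — three printed rows
  discriminate the two.
* **Energy is computed from display-rounded land areas** (1 decimal, 2
  below 500 ha, ties rounding down), matching how the published table was
  evidently produced; `land_available()` returns full precision unless
  `display = TRUE`.

Three published kcal cells still disagree with their own arithmetic by
< 0.005% (one is a plain digit transposition); `capacity_table()` flags
them (`print_discrepancy`) rather than emulating them. The diet-adjusted
summary is the unweighted mean of the six revised scenarios (≈ 1 994
people) plus a 50% supplement for marine and non-mulched terrestrial foods
(≈ 2 990, i.e. ~3 000) — the unweighted mean is the only base that
reproduces the published "~2000" exactly.

```{r capacity}
tab <- capacity_table()
subset(tab, source == "this_study",
       select = c(frequency, n_availability, land_ha, kcal_day, individuals))
unlist(diet_adjusted(tab))
```

## Numerical choices, degenerate inputs, limitations

* Rasters are stored as multi-page 32-bit TIFF plus a JSON sidecar for
  georeferencing; no GDAL binding is required anywhere. Integer digital
  numbers round-trip bit-exactly; arbitrary doubles to ~6e-8. Vector data
  is GeoJSON.
* All areas are computed in projected metres (the grid convention is UTM
  12S); geographic-coordinate math is out of scope.
* Every stochastic step takes an explicit seed and restores the caller's
  RNG state; there is no hidden global randomness.
* Degenerate inputs have defined behaviour: single-class training sets
  classify everything as that class (with a warning at fit time);
  zero-variance PCA skips substitution; empty garden sets survive
  filtering, masking and density mapping; nodata propagates through
  resampling and never enters a training set.
* The minimum-mapping-unit threshold, connectivity, kernel mode, priors
  and penalty are all configurable; defaults are the published protocol
  where one is stated, and the package's own documented choice where not.
* The carrying-capacity model inherits the published framing: sweet
  potato only, rock gardens only, no age structure or temporal dynamics.
  It answers "how many people could this infrastructure feed at steady
  state", not "how many people lived there".
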