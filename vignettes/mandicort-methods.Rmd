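---
title: "Mandibular cortical bone assessment: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mandibular cortical bone assessment: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mandicort)
```

## The screening problem

Osteoporosis and its precursor osteopenia are diagnosed from bone mineral
density (BMD) measured by DEXA, expressed as a T-score in standard-deviation
units relative to the young-adult female mean. The WHO bins are implemented
in `label_from_tscore()`: T ≤ −2.5 is osteoporosis (the boundary included),
−2.5 < T < −1 osteopenia, T ≥ −1 normal. Because DEXA access is limited,
radiomorphometric indices on dental panoramic radiographs — above all the
mandibular cortical width (MCW), the thickness of the bright cortical band
along the inferior mandibular border — are attractive screening surrogates:
the radiograph is routinely acquired anyway.

`mandicort` implements a complete computer-aided pipeline over pre-cropped
regions of interest (ROIs), nominally 128×128 px below the left and right
mental foramen:

1. **Enhancement** — multiscale line operator, then gray-preserving
   multiplication (`multiscale_line_response()`,
   `multiply_preserve_gray()`).
2. **Segmentation** — seeded statistical region merging over a watershed
   over-segmentation (`segment_cortical()`).
3. **Morphometry** — polynomial model of the cortical upper border and a
   width profile measured perpendicular to the border tangent
   (`measure_side()`).
4. **Texture** — mean normalized intensity over the cortical mask, a
   porosity proxy (`normalize_intensity()`, `mean_cortical_intensity()`).
5. **Classification** — 8-feature RBF-SVM (three width summaries per side,
   one texture mean per side) under stratified k-fold cross-validation
   (`cross_validate()`).
6. **Evaluation** — segmentation error metrics ME and RAE, confusion
   matrices, binary screening diagnostics (`misclassification_error()`,
   `binary_diagnostics()`, ...).

A phantom generator (`generate_phantom_pair()`, `generate_dataset()`)
produces class-conditional synthetic ROI pairs with ground truth, so every
stage is testable without patient data.

## Line operator

The line strength of a pixel is

$$S(x) = \max_{\theta}\; \bar g_{L,\theta}(x) - \bar g_N(x),$$

the largest difference, over `n_orientations` evenly spaced angles in
[0°, 180°), between the mean gray along an oriented line segment of
`line_length` pixels through the pixel and the mean gray of the
`neighborhood_size` square around it. Borders are mirror-reflected. The
operator responds to bright elongated structure narrower than the line
length and is exactly zero on uniform images; adding a constant to the
image leaves it unchanged.

Defaults: `line_length = 5`, `n_orientations = 12` (15° steps),
`neighborhood_size = 5`, `pyramid_levels = 4`. The pyramid matters: a
structure *wider* than the line length cancels out of the mean difference,
so the 20–35 px cortical band only responds once it has been decimated
below ~5 px. On a 128 px ROI that requires the 1/8-scale level, hence four
levels rather than the three that would suffice for thin structures alone.
Orientation offsets are rasterized with half-away-from-zero rounding (after
snapping floating-point near-halves), which makes the response exactly
equivariant to 90° rotations whenever `n_orientations` is a multiple of 4 —
a property the test suite asserts.

Per-level responses are upsampled bilinearly to the base grid and fused by
pixelwise maximum; negative (dark-line) responses are clamped to zero
before min–max normalization to [0, 1], since the cortical band is bright
and dark-line responses are noise for this task. The enhanced image passed
to segmentation is the pixelwise product of the ROI with the normalized
response: structure is reinforced while gray-level information — which the
merging statistics need — is preserved.

## Statistical region merging

Four stages, as in seeded region-merging practice:

* **Initial segmentation.** A marker-free watershed of the Sobel gradient
  magnitude of the enhanced image. Basins separated by ridges shallower
  than `gradient_threshold` are merged (EBImage's tolerance mechanism).
  The default is 3 gray levels: the threshold acts on the *enhanced*
  image, whose background sits near zero, and the band's blurred margin
  (a by-product of upsampled coarse responses) produces only shallow
  transitions — a coarser threshold folds that margin into band-edge
  basins and systematically thickens the mask by about a pixel.
* **Sample-area (seed) selection.** Object candidates are *large and
  bright* regions: regions at or above the global area-weighted mean gray,
  ranked by the sum of their descending area rank and mean-gray rank; the
  object seed is the top-5 candidate whose centroid lies nearest the image
  centre (the ROI crop convention puts the band mid-image). The brightness
  pre-filter is essential on noisy inputs, where fragmentation otherwise
  lets large smooth *dark* basins outrank small bright band fragments.
  The background seed is the darkest region whose centroid is farther from
  the centre than the median centroid distance.
* **Distance.** Between a region and a class: the absolute difference of
  the region's mean gray and the class's area-weighted mean gray — the
  simplest statistic consistent with mean-based region merging; it is
  deliberately configuration-swappable.
* **Merging.** Iteratively, the (region, class) pair with the smallest
  distance over all unlabeled regions is merged, class statistics updated,
  until every region is labeled. Ties break to the lowest region id, then
  the object class, making the procedure deterministic. Merging is *not*
  restricted to regions touching a labeled class: the band spans the ROI
  and disconnects the background above it from the background below, so an
  adjacency-constrained background class could never reach the far side
  and everything there would be forced into the object. Connectivity of
  the mask is restored afterwards instead: `segment_cortical()` keeps the
  largest 4-connected component and fills enclosed holes of at most 10 px,
  because the width stage needs one solid band.

## Width measurement

`upper_border()` takes the topmost foreground pixel of every mask column.
`fit_border_polynomial()` fits polynomials of candidate degrees 1–5 by
least squares and selects the degree minimizing 5-fold cross-validated
squared error (folds assigned cyclically in column order; near-ties go to
the lower degree). Raw least-squares error alone would always prefer the
highest degree, so cross-validation is what makes "the best-fitting
polynomial" well-posed. Fits use a centred/scaled design internally and
report raw-column coefficients.

`width_profile()` samples the central 80% of the curve's domain (border
fits are unstable at crop edges; the 10% margins are configurable) at 1 px
column steps. At each sample the tangent slope is the analytic derivative
of the polynomial; the profiler marches from the border point along the
inward unit normal in 0.25 px steps with nearest-neighbour mask lookup
until it leaves the foreground, and reports the distance travelled
(midpoint-corrected by a quarter step for the in/out transition). This is
the decisive construction: for a band tilted by θ, a naive per-column
pixel count errs by a factor 1/cos θ (15.5% at 30°), while the
perpendicular march recovers the true thickness within 5% for rotated
rectangles up to 40° — both properties are asserted in the tests. Widths
are reported in pixels, matching the convention of the reference
measurements.

## Texture

Panoramic radiographs have uneven illumination, so gray levels are first
made comparable: an affine map sends the image's 1st/99th percentiles to
0/255 (percentile anchors resist the bright-band outliers), clipped to
[0, 255]; a constant image maps to the midpoint. The texture feature is
the arithmetic mean of the normalized image over the segmented cortical
mask — porous (osteoporotic) cortical bone contains more dark cavities, so
the mean falls as porosity rises. A `use_mask = FALSE` ablation averages
the whole ROI instead.

## Classification

The canonical feature order is fixed: right min/max/avg width, left
min/max/avg width, right texture, left texture. `train_svm()` standardizes
features to zero mean and unit variance *on the training set only* and
fits a one-vs-one multiclass RBF-SVM (the common default for three
classes). `cross_validate()` builds stratified folds from a seeded shuffle
— stratification protects the smallest class at k = 10 — and chooses
`C ∈ {0.1, 1, 10, 100}`, `γ ∈ {0.001, 0.01, 0.1, 1}` per fold by an inner
stratified 3-fold grid search on the training split. Per-fold
standardization statistics and chosen hyperparameters are retained in the
report so leakage can be audited by recomputation. The same seed
reproduces an identical report. The summary table follows the standard
layout: rows k ∈ {2, 3, 5, 10} plus their average; columns
width+texture / width-only / texture-only; percentages printed rounded
half-up to two decimals (plain `round()` would round 46.535 down).

## Evaluation metrics

* **ME** (misclassification error): the fraction of pixels whose
  foreground/background assignment disagrees with ground truth —
  `1 − (|B∩B'| + |F∩F'|)/N`. Zero for identical masks, one for
  complementary masks, symmetric.
* **RAE** (relative foreground area error): with ground-truth area
  `A_g` and predicted area `A_p`, `(A_g−A_p)/A_g` if the prediction is
  smaller, else `(A_p−A_g)/A_p`; always in [0, 1]. This is the standard
  branch form from the threshold-evaluation literature; the metric is
  named but not written out in the source material.
* **Binary screening diagnostics**: the 3-class confusion matrix collapsed
  with positive = {osteopenia, osteoporosis} ("low bone density");
  sensitivity, specificity, accuracy, LR+ = sens/(1−spec),
  LR− = (1−sens)/spec, with zero denominators reported as `NA` rather than
  errors. Confidence intervals for sensitivity and specificity use the
  Clopper–Pearson exact method; since the CI method of the reference
  tables is unstated, CI values are reported but not asserted against
  printed values.
* **Percent agreement** for rater comparisons is the matching fraction in
  percent.

## The phantom generator

`generate_phantom_pair()` emulates what the pipeline assumes about a real
ROI and nothing more: a bright, gently curved cortical band of constant
perpendicular thickness over band-passed trabecular texture, with
class-conditional width and porosity, an illumination gradient and pixel
noise. Per side:

* Target width drawn from the class's per-side normal distribution
  (truncated at 5 px). The width means and SDs are the published per-class
  feature statistics of the 123-patient reference population (e.g. normal
  right side 27.7 ± 6.4 px; osteoporosis left 21.6 ± 4.4 px) — repurposed
  as *generator* parameters, i.e. the ground truth the pipeline must
  recover, not values it must reproduce.
* A mild degree-2 upper-border polynomial (curvature ±0.002 px⁻¹, slope
  ±0.2, vertical placement 40–55% of the image height) keeps the band
  roughly central, as the ROI cropping convention does on real images.
* The band is rendered with constant *perpendicular* thickness: the
  vertical extent under the border at column c is w·√(1+m(c)²), m the
  border slope.
* Band gray per class: 190/178/166 ± 8 for normal/osteopenia/osteoporosis
  over a trabecular background of mean 80 and SD 12 (band-passed Gaussian
  noise). The published texture values (~41–52) are means of *normalized*
  images over the mask and cannot serve as renderable gray levels, so
  band contrast is a package choice; the class texture signal is instead
  carried causally by porosity: dark holes punched at 0.5/1.5/3.0 holes
  per 100 px of band length (radii 1–3 px), rates chosen so porosity
  rises from normal to osteoporosis.
* Illumination gradient of ±15 gray across the image in a random
  direction, then Gaussian pixel noise (σ = 4), then 8-bit quantization.
  Ground-truth masks are rendered before any noise. "Easy mode"
  (σ = 1, no gradient) is available for oracle tests.

Everything is deterministic given the seed; dataset-level generation draws
per-record seeds once from the master seed.

**What the phantoms do not model** — and hence what passing tests do *not*
show about real radiographs: teeth, the mental foramen, hyoid
superimposition, edentulous ridge variation, scanner-specific noise, or
any correlation structure between width and porosity beyond their shared
class label. Phantom cross-validation accuracies (~60–65% at these class
overlaps) are properties of the generator's distributions, not estimates
of clinical performance; the reference study's real-data numbers are not
reproducible without its images. At the default porosity rates the
texture features raise cross-validated accuracy on average (and reliably
so when measured over ground-truth masks), but the induced texture class
gap (~1–5 gray against a ~5-gray per-subject spread, most of it from the
illumination gradient interacting with the percentile anchors) is small
enough that for individual end-to-end dataset realizations the gain can
fall inside estimation noise.

## Numerical choices and degenerate inputs

* Coordinates are 0-based (row, col) with row 0 at the top everywhere;
  left ROIs are not mirrored (the pipeline is orientation-agnostic per
  side).
* Uniform images: enhancement returns all zeros; a single-region partition
  makes `select_seeds()` fail loudly ("degenerate partition") rather than
  fabricate a mask.
* Constant images under normalization map to the target midpoint.
* Polynomial-degree near-ties (relative CV-error difference below 1e-8)
  resolve to the lower degree, so exact low-order borders select their
  true degree despite floating-point noise.
* Width samples whose normal leaves the image, or whose start pixel is
  background, are skipped; fewer than 3 surviving samples is an error.
* Batch runs isolate per-record failures: one unreadable image marks its
  row and the batch continues.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything they
measure: the end-to-end study uses the reference population's class sizes
(68/38/17 = 123 subjects, 246 ROIs of 128×128), segmentation oracles use
a dozen easy-mode phantoms, geometry oracles use 15 rotated rectangles,
and the metric oracle enumerates all 512×512 pairs of 3×3 masks. These
sizes were chosen to exercise every class and branch while keeping a full
run in the minutes range on one CPU.
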