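---
title: "Quantifying left-ventricular trabeculation by box-counting fractal dimension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left-ventricular trabeculation by box-counting fractal dimension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvtrab)
```

## The measurement problem

Left-ventricular non-compaction (LVNC) is characterised by excessive
trabeculation: muscular ridges projecting from the endocardial surface into
the blood pool, with deep inter-trabecular recesses continuous with the
cavity. Conventional criteria measure a non-compacted/compacted thickness
ratio at a single location, which is sensitive to where the caliper is
placed. The fractal dimension (FD) of the endocardial border summarises the
complexity of the whole trabeculated contour in a single dimensionless
number: a smooth border has FD near 1, a highly convoluted one approaches 2.
`lvtrab` implements a semi-automated FD analysis of short-axis cine CMR at
end-diastole, the construction of age- and sex-specific normative reference
ranges for the resulting measures, classification of new subjects against
those ranges, and the intraclass-correlation statistics used to document the
method's reproducibility.

## The per-slice pipeline

Each end-diastolic slice passes through five stages:

1. **Bicubic magnification** (`magnify()`, default factor 4). Separable
   cubic convolution with the Catmull–Rom kernel (a = −1/2), which
   reproduces constants and linear ramps exactly; pixel spacing is divided
   by the factor. Magnification refines the raster so that the box-counting
   grid resolves trabecular detail; FD itself is scale-free, so the factor
   affects discretisation error, not the quantity being estimated.
2. **Region of interest.** The ROI is conceptually a user decision — a
   circle drawn around the ventricle — supplied per slice. When absent, a
   default is derived from the image (circle on the centroid of the
   brightest intensity decile, radius 1.3 × the equivalent-area radius of
   that region). The default assumes the blood pool is the brightest
   structure and occupies well under a decile of the field of view, which
   holds for full-FOV clinical acquisitions but not necessarily for tightly
   cropped images; it is a convenience, always overridable, and the tests
   exercise the explicit-ROI path that mirrors the intended workflow.
3. **Blood-pool segmentation** (`segment_blood_pool()`). A two-phase
   region-based level set (piecewise-constant model): the ROI intensities
   are rescaled to [0, 1], the contour is initialised from an Otsu
   threshold, and the level-set function evolves under the competing
   data terms of the two phases plus curvature regularisation
   (weight `nu = 0.1`, time step 0.5, smoothed delta width 1.5, iteration
   cap 200, convergence when the mean absolute update over the ROI falls
   below 1e-3). The function is clamped to [−1, 1] so the interior
   saturates and the convergence measure tracks only the moving front. The
   bright phase is taken as pool; the final mask is its largest 8-connected
   component, which keeps inter-trabecular recesses contiguous with the
   cavity and discards isolated bright specks. A plain Otsu-threshold
   segmenter (`segmenter = "threshold"`) is available for noise-free
   fixtures and debugging. Segmentation is fully deterministic.
4. **Border extraction** (`detect_edges()`). The Sobel gradient of the
   binary mask, restricted to the pool side, yields the one-pixel
   endocardial contour including every trabecular and papillary-muscle
   indentation. On a binary image the Sobel response is quantised, so "any
   strictly positive magnitude" is an exact threshold; pool pixels touching
   background whose centred differences cancel by symmetry (isolated pixels,
   one-pixel strands) are kept as border so the contract "a non-empty mask
   with a boundary yields a non-empty border" holds unconditionally.
5. **Box counting and fit** (`box_count()`, `fit_fd()`). A single grid is
   anchored at the top-left corner of the border's bounding box; partial
   boxes at the margins count. Box sides are powers of two from 2 px up to
   the largest power of two not exceeding 45% of the smaller bounding-box
   dimension of the analysis region — boxes larger than that measure the
   object's planar extent rather than its boundary scaling and would bias
   the slope (the full image is used instead when an object is so thin
   that its own bounding box yields fewer than four sizes). FD is minus
   the slope of the unweighted least-squares line of log N(s) on log s;
   R² of that line is reported as a fit diagnostic. Offset averaging over
   grid translations is deliberately omitted: a single anchored grid makes
   the measurement bit-reproducible, and the validation below shows the
   residual anchoring error is well inside the tolerance of interest.

`slice_fd()` composes the five stages; stage failures carry the slice index.

## Stack aggregation

`analyze_stack()` excludes the most apical slice wholesale before analysis —
partial-volume averaging makes its border unreliable — so it contributes
neither to the global mean nor to the regional measures; the exclusion is
recorded in the output. Global FD is the arithmetic mean of the analysed
slice FDs. For regional measures the analysed stack is halved
(`split_halves()`): for an odd number of slices the middle slice is dropped
from the halving only, while still counting toward global FD. Mean apical
and maximal apical FD are the mean and maximum over the apical half.
Base→apex orientation is taken from the stack's declared order; when data
arrive apex-first the caller must say so explicitly (no silent guessing).

## Validation against known fractals

Box counting is validated against rasterisations with analytically known
dimension (`make_fractal()`): a straight line (FD 1), the triadic Koch curve
(log 4/log 3 ≈ 1.2619), the eight-segment quadratic Koch curve
(log 8/log 4 = 1.5) and the Sierpinski triangle (log 3/log 2 ≈ 1.5850), all
on a 1024-px canvas at recursion depths 6, 5 and 7 respectively. The
grid-aligned constructions (line, quadratic Koch, Sierpinski) rasterise
exactly; the Koch curve is drawn by dense sampling of its 4096 segments.
The acceptance script recomputes the mean signed error of the pipeline over
this suite; the test suite additionally checks each fractal individually
and verifies that shrinking the size range by one octave at each end moves
no estimate by more than 0.05.

## The synthetic phantom

`make_lv_stack()` generates bSSFP-like end-diastolic short-axis stacks with
ground truth. Each slice is a bright circular blood pool (default intensity
400) inside a darker myocardial annulus (120) on background (40), with
additive Gaussian noise (default SD 5, i.e. ~2% of the pool–myocardium
contrast) and a multiplicative low-order polynomial bias field (default
amplitude 10%) to exercise the segmenter beyond what a global threshold
could solve. Trabeculae are dark radial fingers with Gaussian angular
profiles: complexity c ∈ [0, 1] maps linearly to the finger count
(up to 24) and depth (up to 0.35 of the endocardial radius), and finger
widths scale with the angular spacing so that fingers remain distinct as
their number grows — without this the bumps merge and the boundary gets
*smoother* with rising c, destroying the intended ordering. Two papillary
bodies attached to the wall appear once the effective complexity exceeds
0.15. The endocardial radius tapers base→apex (55% reduction at the apex,
exponent 1.5) and complexity follows a raised-cosine axial profile peaking
at 60% of the base→apex axis, emulating the mid-ventricular trabeculation
maximum seen in vivo. Canvas 128 px at 1.5 mm spacing and 10 slices per
stack keep a full stack analysis around ten seconds while leaving fingers
several pixels wide after ×4 magnification.

What the phantom does *not* emulate: anatomical shape variation
(non-circular cavities, the right ventricle, chest wall), motion and flow
artefacts, partial-volume averaging at the apex, and the thin compacted
epicardial layer. Passing the phantom grid therefore demonstrates that the
chain recovers known geometry under noise and bias — not that it handles
every clinical image; on real data the ROI and visual QC of the per-slice
overlays remain the analyst's responsibility.

`simulate_cohort()` draws cohort tables (default 500 per sex, ages uniform
20–69, slope 4e-4 FD/year, female/male intercepts 1.177/1.198 — a sex gap
of 0.021 — residual SD 0.029), emulating a healthy adult population with FD
rising slowly with age and higher in males. `simulate_raters()` draws
rating matrices from a subject-plus-rater-shift-plus-noise model with known
variance components.

## Reference ranges and classification

`fit_reference()` fits, per sex, an ordinary least-squares line of the
metric on age and keeps the components (intercept, slope, residual SD s, n,
mean age, age sum of squares) needed for the 95% prediction interval at age
x: ŷ(x) ± t₀.₉₇₅,ₙ₋₂ · s · √(1 + 1/n + (x − x̄)²/Sxx). Reference limits are
those prediction bounds; each limit additionally carries an *indeterminate
region* — its own 95% confidence interval, reflecting that a finite cohort
locates the limits imprecisely. The indeterminate regions are estimated by
case-resampling percentile bootstrap (default 2000 resamples, seeded and
recorded), with a delta-method approximation available behind
`method = "delta"`; the bootstrap is the default because it makes no
normality assumption about the limit estimator and the two agree closely on
well-behaved cohorts (a test asserts this). Classification
(`classify_value()`) is five-way by the four breakpoints:
abnormal-low / indeterminate-low / normal / indeterminate-high /
abnormal-high.

The package also ships decade tables of published reference limits for the
three FD measures and three global strain measures, sexes stratified, ages
20–69 (`packaged_reference()`). When classifying against these tables the
decade row containing the subject's age is used as-is, without
interpolation, matching how printed clinical tables are applied. Strain
values are classified on their signed values exactly as tabulated (pairs
stored in increasing numeric order); strain *computation* is out of scope —
only classification of externally supplied strain values is provided.

## Reproducibility statistics

`icc_2way_random_agreement()` computes the two-way random-effects,
absolute-agreement, single-measure intraclass correlation ICC(2,1) from the
two-way ANOVA mean squares, with the F-based confidence interval for that
variant (Satterthwaite degrees of freedom in the lower bound). Single
measures are the default because each reading in an observer study is a
single measurement, not an average; averaged-measures ICC(2,k) is available
behind `type = "average"`. Missing cells are removed listwise with a
reported count. A perfect-agreement matrix yields ICC 1 with a degenerate
interval.

## Numerical choices and degenerate inputs

- Zero intensity variance in an ROI raises a "no contrast" error rather
  than returning an arbitrary mask; a level set that exhausts its iteration
  cap returns its mask with a convergence warning rather than failing.
- A mask covering its whole ROI has no interior boundary and is rejected.
- An exact power-law box-count curve is recovered to 1e-9; a curve with no
  size variance is rejected.
- Cohorts need at least 10 records per sex spanning at least 20 years of
  age; bootstrap indeterminate regions need at least 200 resamples; ages
  more than 10 years outside the fitted span are refused rather than
  extrapolated.
- All generators are pure functions of (spec, seed): they save and restore
  the caller's RNG state and return bit-identical output for identical
  arguments.

## Problem sizes used by the tests

The test suite runs phantoms at 128-px canvas with ×4 magnification
(512-px segmentation grids), a 15-cell complexity × noise grid with four
slices per cell for segmentation quality and FD-bound checks, five
full-stack analyses for the complexity sweep, cohorts of 500 per sex
(coverage checked on 5000 fresh draws), and rating matrices up to n = 200.
These sizes were chosen so the statistical tolerances quoted above are
several standard errors wide while the whole suite stays in the minutes
range.

## Known limitations

- The level-set contract is this package's own (two-phase piecewise-
  constant model, Otsu initialisation, parameters above); any segmenter
  satisfying the blood-pool mask contract can be plugged in.
- FD characterises border complexity only; it carries no information about
  compacted-layer thickness, and a single global number can mask focal
  abnormality — the apical measures partially address this.
- The packaged decade tables apply to the population, field strength and
  analysis tool they were derived with; new cohorts should use
  `fit_reference()` on their own data.
- DICOM reading requires an external `python` interpreter with pydicom and
  nibabel; NIfTI and image-directory input are native.
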