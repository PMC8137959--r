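---
title: "Nuclear morphometry and optimism-corrected survival validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry and optimism-corrected survival validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmorph)
```

`nucmorph` measures the geometry of segmented tumor-cell nuclei and asks
whether those measurements predict survival. This vignette is the
package's own account of the science: the measurement model and its
conventions, the survival methodology, what the synthetic-data generator
does and does not emulate, and the numerical decisions a maintainer
would want written down.

## The measurement model

The unit of input is one binary mask per nucleus — the standard output
of modern nucleus-segmentation networks applied to H&E-stained
tissue-microarray patches. Throughout the package the image coordinate
convention is: origin at the top-left pixel center, `x` = column, `y` =
row, `y` increasing downward, both 0-based; angles are measured from the
+x axis in these coordinates.

Two deliberate conventions shape every number downstream:

* **Pixel-center geometry.** A pixel belongs to a rasterized shape iff
  its *center* lies inside the analytic shape, and the traced boundary
  passes through pixel centers. Consequently a shape spanning `w` pixels
  has contour extent `w − 1`, and the shoelace area of a disk contour
  sits about 2% below πr² (half-pixel erosion around the whole
  boundary). The payoff is that analytic areas, extents and identities
  are exactly checkable, which the test suite exploits heavily. Masks
  produced by other tracers (sub-pixel marching squares, outer-boundary
  tracers) will differ at this half-pixel level, so bit-compatibility
  with any released feature table is explicitly not promised.
* **Connectivity.** A valid mask has a single 8-connected foreground
  component of at least 5 pixels. Components are counted over a pixel
  adjacency graph and the boundary is traced with Moore-neighbor
  (8-connected) following; both honor the 8-connectivity contract,
  which common 4-connected labeling routines do not.

From the boundary and the foreground pixel centers the package computes
the convex hull (hull and everything derived from it use *all*
foreground pixel centers, which is exact for point sets), and then:

* **Minimum-area rotated rectangle** by rotating calipers: the optimum
  rectangle has a side collinear with a hull edge, so only hull-edge
  orientations are examined; area ties are broken toward the smallest
  angle. The reported `rotate_angle` lies in [−90°, 0): −90° means
  axis-aligned and the angle increases toward 0° as the rectangle
  rotates clockwise. One ambiguity is inherited from the feature
  naming conventions in circulation: `rectCenter` is described in some
  sources as the rectangle's *center* and in others as its *top-left
  point*. `min_area_rect()` returns both (`center`, `top_left`); the
  CSV column `rectCenter` carries the center, and `rect_topleft` is
  written alongside so either convention can be joined against.
* **Feret diameters**: the maximum is the largest pairwise distance
  between hull vertices; the minimum is the smallest caliper width,
  attained perpendicular to some hull edge. `max_angle` is the
  direction of the maximizing chord; `min_angle` is the direction along
  which the minimum width is measured (the supporting edge's normal) —
  the latter is a documented choice, since "the angle of the minimum
  diameter" is not otherwise well defined. Both lie in [−180°, 180°].
* **Fitted ellipse**: the direct algebraic least-squares conic fit with
  the ellipse constraint 4AC − B² = 1, in the numerically stable
  partitioned (scatter-matrix) form, over the traced contour points
  centered for conditioning. Ellipse area is πab. This family of fits
  has a small known bias toward smaller, rounder ellipses on noisy
  boundaries; on rasterized masks the recovered axes sit ~1–2% below
  the analytic values, dominated by the half-pixel contour erosion. A
  moments-based fit (covariance of the boundary ring; eigenvalue λ ≈
  (semi-axis)²/2) is available as `method = "moments"` and as the
  automatic fallback when the algebraic fit degenerates to a
  non-ellipse conic (possible for very short or degenerate contours).
* **Ellipse perimeter** by Ramanujan's second approximation,
  `π(a+b)(1 + 3h/(10 + √(4−3h)))` with `h = ((a−b)/(a+b))²`. Exact in
  the circle limit; relative error below 1e−6 for axis ratios down to
  ~0.2 and below 0.5% even in the fully degenerate limit, as asserted
  in the tests against arc-length quadrature.

The six derived shape factors (`esf`, `csf`, `sf1`, `sf2`, `elongation`,
`convexity`) are simple ratios of these quantities; all but `convexity`
equal 1 for a perfect circle, `elongation · sf2 = 1` identically, and
`csf` decreases strictly toward 0 along ellipses of fixed area and
growing elongation — all properties the suite verifies on rasterized
shapes. Lengths are reported in pixels; the physical scale of a 40x
scan (0.25 µm per pixel) is applied only to optional `*_um` columns,
never silently.

## Patch extraction

ROI annotations are axis-aligned rectangles (upper-left and lower-right
corners at full magnification). The package treats rectangles as
0-based and half-open, `[x0, x1) × [y0, y1)`, which makes the tiling
arithmetic exact: windows of `size` pixels (default 224) advance by
`stride` (default 224) from the ROI's top-left corner, row-major, and
windows that do not fit are dropped, never padded — so the retained
count is exactly `⌊w/stride⌋·⌊h/stride⌋` for an all-tissue ROI. A patch
is discarded as "mostly white" when the fraction of pixels with all
three channels above `white_level = 220` strictly exceeds
`max_white_fraction = 0.5`; both knobs are exposed in the configuration
because the underlying criterion ("little tissue") is qualitative, and
the at-threshold case is kept by design.

## Survival validation

Per-patient feature vectors are the mean and sample (n−1) standard
deviation of each geometric feature over the patient's nuclei; the
denominator is a documented choice, as is column-mean imputation of
missing clinical covariates (after the patient join, before
standardization; complete-case analysis is available via
`impute = "complete"`). All covariates are z-scored before Cox fitting —
this improves Newton–Raphson conditioning and makes coefficients
comparable across features; it does not change concordance-based
metrics, which are rank statistics of the linear predictor.

Cox models are fitted by `survival::coxph` with **Efron tie handling**
(the defensible default when event times tie), gradient tolerance 1e−7
and up to 100 iterations. Monotone partial likelihood (risk separation)
and singular information are converted from warnings into errors naming
the suspect column, because a silent pseudo-fit would poison every
bootstrap replicate downstream.

**Harrell's C-index** is computed over comparable pairs — subject *i*
with an observed event and subject *j* with a later time, or an equal
time with *j* censored — counting 1 for a concordant ordering and 0.5
for tied scores. Tied event times are not comparable. The
implementation is a vectorized pairwise computation; the suite checks
it exactly against an explicit O(n²) enumeration oracle and against
`survival::concordance`.

**Optimism correction**: the apparent C of the full-data fit is reduced
by the mean over bootstrap replicates of
`C(replicate fit on replicate) − C(replicate fit on original data)`.
Replicates whose fit fails (separation is common in small resamples)
are skipped and counted; more than 10% failures is an error, since then
the correction no longer estimates what it claims. Replicate *r* draws
its resampling indices from a seed derived deterministically from
`(seed, r)`, so results are reproducible and order-independent.

**Confidence intervals.** A strict CI for an optimism-corrected
statistic requires a double bootstrap. The package instead reports the
percentile interval of the replicate-wise test-on-original C values
from the same replicates — cheap, reproducible, and close to the
corrected estimate when overfitting is mild. Under heavy overfitting
(many covariates per event) the interval centers on the mean
test-on-original C, which can sit *above* the corrected point estimate;
the report carries both so the discrepancy is visible rather than
hidden. This is the main methodological caveat of the package.

## What the synthetic generator emulates — and what it does not

`gen_cohort()` is the package's stand-in for a real cohort, and its
defaults are the study conditions under which the package validates
itself:

* 170 patients (the size of a typical single-institution DLBCL TMA
  cohort), 30 nuclei per patient by default;
* overall survival in years from a Cox model with exponential baseline,
  rate 0.2/year (median ≈ 3.5 years, plausible for DLBCL), sampled by
  inverse CDF — `T = −log(U)/(λ₀·exp(xβ))` — so the generating model is
  exactly the fitted model and coefficient recovery is a meaningful
  check;
* independent exponential censoring at 0.086/year, giving ≈ 30%
  censoring (`P(censored) = c/(c+λ₀)` under the null);
* standard-normal covariates with default true coefficients
  `β = (0.8, 0.3)`;
* nucleus mean radii uniform on 5–30 px (diameters 10–60 px at
  0.25 µm/px) — the size range is a free choice, since the empirical
  nucleus-size distribution of real cohorts is not part of the package's
  inputs;
* a risk→shape coupling (`default_shape_effect`): a patient's linear
  predictor shifts the axis ratio of their nuclei from ≈ 0.95 (low
  risk, round) toward ≈ 0.3 (high risk, elongated), so geometric
  features genuinely carry survival signal and the end-to-end claim
  "shape predicts outcome" is testable with a known ground truth.

Nuclei are star-convex irregular blobs (random radial jitter on a
24-gon), which guarantees valid single-component masks while exercising
non-elliptical geometry. Occasionally a very thin, irregular tip
rasterizes to a disconnected sliver under the pixel-center rule; the
generator retries such a nucleus with a deterministically perturbed
blob seed rather than relaxing the mask contract. Slides from
`gen_slide()` are near-white (≥ 245) outside rectangular "tissue"
regions and dark-textured inside, which is all the patch stage's
whiteness rule can see.

The generator deliberately does **not** simulate staining color or H&E
texture realism, segmentation-model errors (merged/split nuclei, ragged
boundaries), spatial correlation between neighboring nuclei, or
non-proportional hazards. Passing tests therefore demonstrate that the
measurement chain and the validation statistics are correct — not that
real DLBCL nuclei carry this much signal, nor that a real cohort's
censoring is independent exponential.

## Numerical choices and degenerate inputs

* Masks with fewer than 5 foreground pixels, multiple 8-connected
  components, or (for generated masks) foreground within 2 px of the
  grid border are rejected with errors carrying the mask identifiers.
* Contours with fewer than 4 boundary points cannot be traced ("too few
  boundary points"); collinear point sets have no hull; degenerate
  hulls have no rectangle or Feret result. Each stage fails loudly with
  the nucleus id rather than propagating NaNs.
* Rectangle-orientation ties (e.g. an axis-aligned rectangle, where the
  0° and 90° calipers give equal area) resolve to the smallest
  reported angle; both orientations map to −90° under the angle
  convention, so the reported angle is exact there.
* NPY I/O: writes version 1.0, dtype `|u1`, C order; reads versions
  1.0/2.0, C or Fortran order, and any integer/boolean/float dtype that
  can hold a binary mask, rejecting anything non-2-D or non-binary with
  the offending path. Cell numbers are not assumed consecutive.
* All randomness flows through explicit seed arguments; generator
  functions save and restore the caller's RNG state.

## Problem sizes used in the tests

The suite validates stochastic claims at sizes chosen to make
Monte-Carlo bands tight while keeping the default run fast: the null
concordance check uses a 2000-subject cohort and 20 score replicates
(3·SE band ≈ 0.004); the null optimism-corrected pipeline uses
n = 100 with 200 replicates; coefficient recovery uses n = 200 with the
RMSE comparison at n = 100 vs 400; oracle-equivalence suites sweep 100
random blob fixtures for the calipers and 50 censored instances for the
concordance enumeration. End-to-end signal propagation uses 200
patients with 12 nuclei each and hazard loading β = (2, 0) on the
shape-coupled covariate. These are the package's own validation
conditions; larger cohorts simply sharpen the same comparisons.

## Known limitations

* The fitted-ellipse bias and half-pixel contour erosion mean absolute
  axis lengths are accurate to ~1–2% on realistic nucleus sizes; ratios
  (the shape factors) are substantially more stable.
* The percentile CI's single-bootstrap nesting, discussed above.
* Whiteness filtering is a threshold rule on RGB values; it does not
  attempt stain-specific tissue detection.
* The package consumes segmentation masks; it has no opinion on
  segmentation quality, and garbage masks yield garbage features
  (subject only to the validity checks above).
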