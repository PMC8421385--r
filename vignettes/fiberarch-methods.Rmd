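---
title: "Methods: quantifying fibrotic versus regenerative collagen architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying fibrotic versus regenerative collagen architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberarch)
```

`fiberarch` measures the structural signature that distinguishes fibrotic
from regenerative healing in 2-D fiber-stained micrographs. This vignette is
the package's account of the underlying models, the parameters that matter,
the numerical choices, and the limits of what the synthetic validation can
show.

## Orientation model

Fiber orientation is *axial*: a fiber at angle θ is the same fiber at
θ + π. All orientation work therefore happens on doubled angles, where
ordinary circular statistics apply. The package convention is radians,
measured counterclockwise from the image +x (column) axis, reported on
[0, π).

### Intensity-gradient detection

`subregion_orientations()` tiles the image into square subregions (default
5 × 5 px, a deliberately small tile so that a tile rarely spans more than
one fiber; configurable). Within a tile, each pixel's Sobel gradient
(magnitude m, direction φ) votes with weight m for the doubled direction
2φ; the tile's fiber angle is half the resultant direction rotated by 90°,
because intensity gradients run across fiber edges, not along them. The
detector assumes locally straight, edge-like structures wider than a pixel
and narrower than a tile; it does not separate overlapping orientations
within one tile.

Two rejection rules remove meaningless tiles:

* tiles whose total gradient magnitude falls below a quantile of all tiles
  (default the 25th percentile) — a *relative* background rejection, since
  absolute gradient levels depend on staining and exposure;
* a numerical floor (10⁻⁹ of the maximum tile weight), because FFT-based
  blurring leaves ripple-level gradients in empty regions that would
  otherwise anchor the quantile;
* tiles touching the mask complement, when a tissue mask is supplied.

One further numerical choice: the outermost one-pixel ring of the gradient
images is zeroed. Replicate-padding at the frame border forces the gradient
component across the border to zero, which biases border-tile angles toward
the border axis; excluding the ring removes that bias at negligible cost.

### Alignment statistics

The mean vector length over retained tile angles,
MVL = ‖mean(cos 2θ, sin 2θ)‖, is 0 for isotropic and 1 for perfectly
aligned fields. Two variants are reported: unit weights (each tile votes
once — the default, so a large faint region counts as much as a small
bright one) and gradient-magnitude weights (`weighted = TRUE`, more robust
on sparse images where many retained tiles are weak). On sparse, noisy
fields the unit-weight MVL is attenuated by background votes; raising the
cutoff quantile or weighting restores contrast. Both variants enter the
default feature panel, so the downstream axis does not depend on the
choice.

Angle kurtosis is defined as the *excess* kurtosis (Gaussian ⇒ 0) of the
angle sample after recentring the circular mean of doubled angles onto the
interval midpoint and unwrapping to a linear sample. A uniform angle
distribution gives −1.2 (the value the test suite checks against a
Monte-Carlo oracle; the data-dependent recentring introduces a bias of
order 10⁻³ that the oracle band absorbs). Perfectly concentrated samples
have zero variance: `angle_kurtosis()` raises an error by default and
returns an `Inf` sentinel when configured, which the panel assembly treats
as a missing value subject to the imputation policy.

## Fiber tracing

`extract_fibers()` is a deliberately simple individual-fiber tracer:
Gaussian smoothing (σ = 1 px) → Otsu threshold → Zhang–Suen thinning →
spur pruning → junction splitting → path tracing. Design notes:

* **Junctions** are skeleton pixels with Rutovitz crossing number ≥ 3 (the
  count of 0→1 transitions around the pixel). The raw 8-neighbor count
  misclassifies staircase pixels of diagonal runs as junctions and
  shreds straight fibers. Fibers are *split* at junctions, never linked
  across them: deterministic, at the cost of fragmenting genuinely
  crossing fibers (a known limitation shared with the design choice of
  any non-linking tracer).
* **Spurs** — side branches shorter than `min_fiber_len_px` (default
  10 px) that terminate at a junction — are deleted before splitting, so a
  long fiber with a small barb is not cut in two at the barb.
* **Arc length** is measured on the traced path subsampled every 4 pixels;
  per-pixel steps on an 8-connected staircase overestimate a diagonal
  segment's length by up to 8%.
* **Width** is the mean over centerline pixels of 2d − 1, where d is the
  Euclidean distance transform of the foreground: for a ribbon of odd
  width w the centerline sits at distance (w + 1)/2 from background, so
  2d − 1 recovers w exactly where 2d alone is biased by one pixel.
* **Curvature** is reported as 1 − straightness (straightness =
  chord/arc); **localized density** is the mean centerline-pixel fraction
  in a `box_px` window centered on centerline pixels (density local to the
  fibers), while **box density** averages over a fixed tiling of the whole
  frame — the two answer different questions and both enter the panel.

## The fibrosis–regeneration axis

`assemble_panel()` builds one row per sample from the orientation and fiber
summaries over an ordered feature schema. The default schema has 24
features — seven orientation statistics and seventeen fiber morphometrics
(`default_feature_schema()`); it is configurable because panels of this
kind differ in which morphometrics their upstream tools emit. Missing
values are an error naming the sample and feature unless median imputation
is requested; zero-variance columns are an error at PCA time, not a silent
drop, since silently losing a column corrupts the panel contract.

`fit_pca_axis()` centers and scales every feature to unit variance and
eigendecomposes the correlation structure. PCA signs are arbitrary, so PC1
is flipped if needed to make the MVL loading positive: alignment rises
with fibrosis, hence "fibrotic scores positive" is deterministic.
Projection of new panels uses the *stored* center and scale, not the new
panel's own moments.

The planted-effect validation (`gen_planted_panel()`) shifts three features
(including `mvl`) by 10 within-group standard deviations in one of two
groups. After unit-variance scaling a k-feature planted block contributes a
correlation eigenvalue of about 1 + (k − 1)ρ ≲ k, which must clear the
Marchenko–Pastur noise edge (1 + √(p/n))² for PC1 to lock onto the planted
axis rather than sampling noise; with p = 24 and k = 3 that requires on the
order of 50 samples, so the planted simulation uses 25 per group. This is
a property of correlation-matrix PCA at n ≲ p, not of the implementation:
at the study scale of ~31 samples an axis dominates only because real
collagen features are strongly mutually correlated, effectively a large k.

## Strain from tracked markers

`fit_deformation()` solves the overdetermined linear system x = **F**X +
**p** for the 2-D homogeneous deformation gradient and translation by QR
factorization of the design [X₁ X₂ 1]. At least three non-collinear
markers are required; the condition number of the design is reported and a
value above 10⁸ is rejected as rank-deficient. `residual_rms` is the RMS
over all 2n scalar residual components, so for isotropic noise σ its
expectation is σ√(1 − 6/(2n)) (six fitted parameters). The model is
strictly homogeneous: spatial strain gradients across the marker field are
averaged, not resolved.

Green–Lagrange strain is the standard **E** = ½(**F**ᵀ**F** − I), which
vanishes for any rigid motion. Conversions that square the right
Cauchy–Green tensor, **E** = ½((**F**ᵀ**F**)² − I), appear in some
descriptions; that form is dimensionally anomalous as a strain measure, so
it is offered only as `form = "printed"` for comparison and is not the
default. Principal strains sort descending with ties broken by ascending
direction angle, and eigenvector signs are fixed (first nonzero component
positive) for reproducibility. `equibiaxial_strain_percent()` reports
100(√λᵢ(**F**ᵀ**F**) − 1), the engineering stretch a "10% equibiaxial
strain" protocol targets.

## Percent-positive area

`percent_positive_area()` counts pixels above threshold inside the analysis
mask. Per-image Otsu is the default because absolute fluorescence
intensities are not comparable across sections; a fixed threshold is
provided for batch comparability, and the threshold actually used is
always recorded. A constant image makes Otsu degenerate: the function
warns and reports 0% by definition. For trichrome collagen quantification
the `blue_dominant` channel restricts the mask to pixels with B > R and
B > G before thresholding blue — a deliberate simplification; no stain
color deconvolution is attempted.

## What the synthetic data does and does not emulate

The generator draws straight, constant-width, anti-aliased fibers with
doubled-angle von Mises orientations, lognormal lengths, Gaussian PSF blur
and additive Gaussian noise; marker grids under exact affine maps with
localization noise; binary/blob area images with exact pixel-count truth;
and Gaussian feature panels with planted group shifts. Defaults (256² px
tiles, ~40 fibers of ~80 × 3 px, blur σ = 1 px, noise σ = 0.02) describe
long thin fibers in a high-magnification field. `placement = "nonoverlap"`
enforces a separation of one fiber width plus the blur halo so that
rendered fibers remain resolvable — the regime in which count recovery is
well-posed; under crowding the generator redraws a fiber from the same
distributions rather than fail.

Real micrographs differ in ways the generator does not model: fibers
curve, branch, bundle and cross; birefringence produces orientation-dependent
intensity; illumination is non-uniform; and section thickness projects 3-D
structure into the plane. Passing the synthetic suite therefore
demonstrates correctness of the *measurement machinery* on resolvable
fiber fields with known truth — not segmentation robustness on crowded
histology, for which the weighted MVL and mask support are the practical
mitigations.

## Validation scales and numerical conventions

The test suite runs the generators at sizes chosen to keep the full suite
fast while leaving sampling error far below the tolerances checked:
10⁴-angle samples for the von Mises/Bessel-ratio consistency checks
(compared within 3 delta-method standard errors), 20 twelve-fiber images
for count/length recovery, 100 seeds for planted-axis recovery, 50 random
affine maps (recovery to 10⁻¹⁰ relative error; strain rotation invariance
to 10⁻¹²), and 1000 null simulations for type-I calibration against the
binomial 95% band. Orthonormality of loadings is asserted to 10⁻⁸.
All randomness flows through explicit seed arguments (`withr::with_seed`);
no function touches the global RNG state.

## Known limitations

* No curvelet/Fourier orientation analysis and no fiber linking across
  crossings; crowded fields undercount fibers and shorten traced lengths.
* The homogeneous deformation model cannot report strain heterogeneity.
* Per-image Otsu thresholds drift with staining intensity; use the fixed
  mode when comparing absolute areas across batches.
* The 24-feature default schema is one reasonable instantiation of a
  collagen-architecture panel, not a canonical set; axis loadings are
  interpretable only relative to the schema used.
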