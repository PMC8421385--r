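# fiberarch

Quantitative analysis of collagen fiber architecture in tissue micrographs,
for researchers studying wound healing, scarring, and tissue mechanics.

Fibrotic healing (e.g. hypertrophic scarring) lays down long, strongly
aligned collagen fibers; regenerating or unwounded skin keeps a basket-weave
network of shorter, isotropically oriented fibers. `fiberarch` turns 2-D
fiber-stained micrographs (Picrosirius Red under polarized light,
immunofluorescence) into per-sample numbers that separate those two states,
and adds the companion measurements such studies need: marker-based strain
estimation for stretched scaffolds and percent-positive-area quantification
for stained sections. A synthetic-data generator with exact ground truth
makes every stage testable without any imaging data.

## What it computes

**Orientation and alignment.** Fiber orientation is axial (θ ≡ θ + π), so
angles are analyzed at doubled angles. In each small subregion, pixel
intensity gradients (Sobel) vote in doubled-angle space, weighted by
gradient magnitude; the subregion's fiber angle is the half-resultant
direction rotated 90°. Over the retained subregion angles θᵢ, the strength
of alignment is the mean vector length

    MVL = ‖ (1/n) Σᵢ (cos 2θᵢ, sin 2θᵢ) ‖ ∈ [0, 1],

0 for completely random fiber alignment and 1 for completely aligned fibers.
The angle histogram, circular mean/SD, and the excess kurtosis of the
recentred angle distribution come with it.

**Per-fiber morphometrics.** Individual fibers are traced by smoothing,
Otsu thresholding, Zhang–Suen skeletonization, spur pruning, and splitting
at skeleton junctions; each fiber reports arc length, medial-axis width,
end-to-end angle, and straightness, summarized per sample together with
feature number (fibers per unit area), box density, and localized density.

**Fibrosis–regeneration axis.** The per-sample summaries populate a
24-feature panel (schema configurable). PCA with centering and unit-variance
scaling defines the axis; the PC1 sign is fixed so the MVL loading is
positive, making "more fibrotic" deterministically positive. Group
comparisons (ANOVA + Tukey, t-tests) are reported with means ± SEM.

**Strain from tracked markers.** For matched marker sets (default a 3 × 3
nine-dot grid), the homogeneous deformation x = **F** X + **p** is fit by
least squares, converted to Green–Lagrange strain **E** = ½(**F**ᵀ**F** − I),
and reported as principal engineering stretches in percent.

## Worked example

```r
library(fiberarch)

sim   <- gen_fiber_image(fiber_sim_params(n_fibers = 25, kappa = 3,
                                          mean_angle = pi/3, seed = 7))
field <- subregion_orientations(sim$image, weight_cutoff_quantile = 0.75)
alignment_summary(field, weighted = TRUE)
#> <alignment_summary> n = 651, MVL = 0.863, mean angle = 60.9 deg, kurtosis = 3.64

fit <- fit_deformation(gen_marker_pair(diag(c(1.1, 1.1)), p_true = c(4, -3),
                                       noise_sigma = 0.05, seed = 1))
fit
#> <deformation_result> n = 9 markers
#> F = [1.0979 0.0026; 0.0029 1.0994], p = (4.009, -2.996), residual RMS = 0.0382
equibiaxial_strain_percent(fit)$percent
#> [1] 10.15  9.58
```

The simulated field was drawn with a von Mises orientation concentration of
κ = 3 around 60°; the measured MVL of 0.863 sits near the ground-truth MVL
of the sampled angle set (0.897), and the measured mean angle recovers the
planted 60° axis. The marker fit recovers the imposed 10% equibiaxial
stretch to within the marker localization noise.

## Analysis workflow

The `analysis/` scripts run a complete synthetic study and write their
tables under `results/`:

1. `01_simulate_cohort.R` — 31 images in four groups (9/9/7/6): two
   fibrotic (aligned, long fibers) and two regenerative (isotropic, short).
2. `02_architecture_axis.R` — orientation + fiber metrics → 24-feature
   panel → PCA axis → Tukey contrasts on PC1. On the simulated cohort PC1
   separates the fibrotic from the regenerative groups (Tukey-adjusted
   p < 1e-6 for every fibrotic-vs-regenerative contrast, n.s. within each
   pair).
3. `03_strain_recovery.R` — twenty noisy nine-marker replicates of a 10%
   equibiaxial stretch, recovered to ~0.2%.
4. `04_area_quantification.R` — percent-positive area vs generator truth,
   exact on binary fixtures.

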