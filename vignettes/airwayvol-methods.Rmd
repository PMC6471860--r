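---
title: "Methods: quantitative CT of airway-tree and lung volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative CT of airway-tree and lung volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biomarker and its rationale

Airflow obstruction in COPD reflects both a smaller airway tree and a
larger, hyperinflated lung, and the two interact: the parenchyma tethers
the airway outer wall, so airway size should be judged *relative to* lung
size.  The central index computed by `airwayvol` is the **airway volume
percent**,

$$\mathrm{AWV\%} = 100 \cdot \frac{\mathrm{AWV}}{\mathrm{rLV}},$$

where AWV (ml) is the lumen volume of the segmented airway tree in the
right upper + right middle-lower lobes and rLV (ml) is the right lung
volume.  The right lung is used because left-sided airway segmentation is
degraded by cardiac motion.  Companion indices are the total airway count
(TAC, the number of skeleton branches in the two lobar subtrees), the
luminal area Ai and wall area percent
$\mathrm{WA\%} = 100\,\mathrm{WA}/(\mathrm{Ai}+\mathrm{WA})$ from
full-width-half-maximum (FWHM) cross-sections, the emphysema surrogate
LAV% (fraction of lung voxels strictly below −950 HU), and size
normalizations AWV/pTLC, rLV/pTLC, and $\mathrm{Ai}/V^{2/3}$ with volumes
in mm³ so the ratio is dimensionless.

## Pipeline stages and their parameters

**Orientation convention.** Volumes are handled in a canonical axis order:
x right→left, y anterior→posterior, z inferior→superior; voxel indices are
1-based in R with world mm coordinates `origin + (index − 1) · spacing`.
Volumes are reported in ml (mm³/1000).

**Airway segmentation** (`grow_airway_tree`) is iterative-threshold region
growing from a trachea seed: the region of voxels below a threshold and
connected to the seed is grown while the threshold relaxes from −960 HU
toward −850 HU in 4 HU steps (26-connectivity).  If the region volume
jumps by more than a factor 2 between consecutive thresholds, the growth
has leaked into the parenchyma and the previous threshold is kept
("leakage rollback").  All parameters sit in `seg_params()`; the accepted
threshold and rollback flag are attached to the returned mask.  There is
no manual-editing path; externally produced masks can be imported with
`read_mask()`.

**Skeletonization** (`skeletonize_mask`) is sequential topology-preserving
3-D thinning: border voxels are deleted over six directional
sub-iterations when they are *simple points* (deletion changes neither the
number of 26-connected object components nor the 6-connected background
components in the 18-neighbourhood) and not curve endpoints.  Sequential
deletion with re-checking guarantees exact topology preservation, so a
tree-shaped mask yields a cycle-free centerline.

**Branch graph** (`build_branch_graph`): skeleton voxels of 26-degree ≠ 2
become nodes (adjacent junction voxels are merged into one node); each
maximal degree-2 chain becomes a branch with its polyline length in mm.
The root is the most cranial endpoint; generations count bifurcations from
it.  Terminal spurs shorter than 2 mm (voxelization artifacts — shorter
than any genuine branch at clinical resolution) are pruned and chains
re-merged; pruning iterates to a fixed point and is idempotent.  Lobe
subtrees are labelled from two supplied root branches
(`partition_subtrees`); automatic anatomical detection of RB1/RB10 is out
of scope, and `auto_lobe_roots()` simply takes the two generation-1
branches, which is exact on phantoms.  TAC counts RUL + RMLL branches
only; the trachea/main stem is excluded.

**AWV** assigns each lumen voxel to its nearest centerline point and sums
voxels whose branch is labelled RUL or RMLL; subtree volumes are therefore
exactly additive.

**FWHM cross-sections** (`extract_cross_section`, `fwhm_measure`): a plane
orthogonal to the 5-point moving-average-smoothed centerline tangent is
resampled at 0.1 mm by trilinear interpolation; 64 rays are cast from the
centre.  Per ray, the lumen minimum and wall-peak HU are found; the inner
boundary is the first outward crossing of (min + peak)/2, the outer
boundary the crossing of (peak + plateau)/2 beyond the peak, with the
plateau the median HU over the last quarter of the ray (robust to vessels
touching the wall).  Rays without a distinct peak are excluded; a measure
with more than 25% failed rays is invalid.  Ai and the outer area are
polygon areas of the boundary points.  Branches are sampled at 25/50/75%
of their length and averaged; paths (e.g. RB1 and RB10 surrogates) are
averaged with equal weight, matching the "average of the two paths"
convention rather than pooling all cross-sections — the source convention
is not stated, so the equal-weight choice is documented here.

**Lungs** (`segment_lungs`): voxels below −320 HU, minus components
touching the lateral border (outside air), keeping the largest two
components above 5 ml, 3-D hole filling, and subtraction of the airway
lumen so tracheal air is not counted as lung or emphysema.  Left/right
split is by component centroid relative to the mid-sagittal plane, with a
minimum-sagittal-cut fallback for fused lungs.  LAV% uses a strict `<`
at −950 HU exactly as printed in density-mask practice.

**pTLC**: the default reference equation is the ECSC male equation
`7.99 · height(m) − 7.08` litres, held in a registry
(`register_ptlc_equation`) because published cohorts differ in which
male TLC reference they use; any fixed reference preserves the role of
pTLC as a body-size adjustment, and swapping equations requires no code
change.

**GOLD grades** use the standard %FEV1 cut-offs with inclusive lower
bounds (≥ 80 → 1, 50–79.99 → 2, 30–49.99 → 3, < 30 → 4); `symptomatic`
means CAT ≥ 10, inclusive.

## The digital phantom: what it emulates and what it does not

`build_tree_spec()` generates a full binary tree of straight cylindrical
branches: radius and length taper geometrically (`taper^generation`,
default taper 0.8, root radius 4 mm, root length 18 mm, half-angle 35°,
branching plane rolled 90° per generation).  Wall thickness is
0.3 × radius with a 1 mm floor so voxelized walls stay watertight at
0.5 mm spacing.  Straight cylinders are chosen deliberately: they give
closed-form truth (volume Σπr²L, Ai = πr², WA% from the annulus) against
which every stage is checked.

`rasterize_phantom()` embeds the tree in a body-filled grid with two
ellipsoidal lungs — a large right lung centred on the tree so
intrapulmonary branches are surrounded by parenchyma, and a smaller left
lung at the patient-left side.  HU levels (lumen −1000, wall 0,
parenchyma −870, emphysema −980, body +40) straddle the −950 HU threshold.
Emphysema is placed by seeded sampling of exactly
`round(fraction · N_parenchyma)` parenchyma voxels (optionally clustered
blobs), so LAV% has a voxel-exact truth.  Gaussian blur (default
σ = 0.6 mm, emulating the scanner point spread) and noise apply to the CT
volume only; truth masks stay crisp.

The phantom does **not** emulate realistic anatomy (cardiac silhouette,
fissures, vessels), scanner reconstruction kernels, or motion; passing the
phantom suite demonstrates the correctness of the measurement chain, not
clinical accuracy on patient scans.  No intensity calibration to any
specific scanner/kernel is attempted.

### Validation conditions used by the tests

Ground-truth recovery (TAC exactness, AWV within 15%, lung/airway Dice,
LAV% exactness) is asserted on *noise-free, blur-free* phantoms at 0.5 mm
spacing on 192³ grids, depths 1–4: with blur the threshold-bounded region
growing cannot reach the half-intensity lumen boundary without leaking
through the −870 HU parenchyma, so it systematically under-segments — the
same underestimation affects commercial airway software and motivates the
ratio form of AWV%.  FWHM accuracy is asserted on blurred annuli
(σ = 0.6 mm, wall 2 mm — a typical segmental wall and comfortably above
the ~2σ thickness the half-max principle needs for a developed wall peak)
and on blurred 3-D phantom branches at σ = 0.3 mm where walls are ≥ 1 mm.
The unit suite uses 128³–160³ grids at 0.5–0.75 mm so the default test run
completes quickly; the end-to-end and acceptance checks use the full 192³
size.

### Known FWHM limitation

The half-max estimator underestimates small lumens: the blurred edge of a
dark disk crosses the (min + peak)/2 level inside the true radius, and the
bias grows as the radius approaches the blur width and as the wall thins
(an attenuated wall peak lowers the half level further).  Measured on the
annulus family at σ = 0.6 mm, wall 2 mm: −16% (r = 2 mm), −9% (r = 3 mm),
−6% (r = 4 mm), −4% (r = 5 mm); even with a fully developed peak
(wall 3 mm) r = 2 mm remains ≈ −10%.  The test suite pins this bias
ordering as a documented property.  Consequently Ai at r = 2 mm does not
meet a 10% accuracy bound under σ = 0.6 mm blur with any anatomical wall
thickness — a physical limit of the principle, not an implementation
defect; thin-walled and small airways should be interpreted accordingly.

## The simulated cohort

`simulate_cohort()` draws CT indices and demographics from a multivariate
normal with means/SDs on the scale of a typical elderly male COPD cohort
(n = 147, age 71 ± 9 yr, LAV% 29 ± 9, WA% 58 ± 5, TAC 212 ± 51,
AWV% ≈ 0.52 ± 0.14%) and generates %FEV1 (61 ± 20) and RV/TLC (42 ± 7) as
linear combinations of z-scored predictors with standardized coefficients
matching published multivariate effect sizes (%FEV1: LAV% −0.50,
WA% −0.26, TAC 0.21, AWV% 0.35; RV/TLC: 0.24, −0.17, −0.17, −0.28) plus
Gaussian noise; by default the residual SD is set to
$\sqrt{1 - \beta^\top R \beta}$ so outcome variance is preserved.  CAT
scores come from a latent score anti-correlated with AWV%; an exact
symptomatic count can be requested for worked-example checks.  The
generator validates positive-semi-definiteness of the correlation matrix
and is seed-deterministic.  It emulates linear association structure only
— no floor/ceiling effects, missingness, or measurement error.

## Statistics layer

Pearson correlations use the product-moment formula with pairwise-complete
cases and the t-transform p-value (n − 2 df).  `fit_standardized_ols`
z-scores the outcome and all independent variables with the sample SD
(n − 1) and fits OLS, so coefficients are standardized βs; the VIF of
predictor j is $1/(1-R_j^2)$ from regressing j on the other independent
variables.  Default covariate adjustment is age, BMI, pack-years and
CT-measured total lung volume.  Group comparisons use Welch's t-test by
default (the pooled-variance variant is available); the GOLD-grade
comparison is fixed-effects one-way ANOVA.  Missing data are handled
complete-case per model with the case count reported; no multiple-testing
correction is applied, matching the raw-p-value reporting convention of
clinical CT studies.

## Numerical choices and degenerate inputs

* Geometry identity between a mask and its reference grid is enforced to
  1e−4 mm (spacing) and 1e−3 mm (origin); any mismatch is an alignment
  error rather than a silent resample.
* Region growing with a seed at or above the first threshold, an empty
  region, an empty mask to thin, an empty LAV region, a single populated
  GOLD grade, or groups smaller than 2 all raise typed errors named in the
  message (`invalid-seed`, `empty-input`, `undefined-measure`,
  `insufficient-groups`, `insufficient-data`).
* Junction clusters in the skeleton (several ≥ 3-degree voxels touching)
  are merged into a single node at their rounded centroid; ties in chain
  tracing are broken by first-neighbour order, which is deterministic.
* Cross-section sampling clamps interpolation at the volume border; rays
  are stepped at half the plane resolution with linear interpolation of
  the half-max crossing.
* All randomness (phantom noise/emphysema, cohort simulation, pipeline) is
  controlled by explicit integer seeds; rerunning a pipeline with the same
  seed and configuration produces byte-identical metrics JSON.

## Reproducing the headline numbers

`scripts/acceptance.R` regenerates everything end-to-end (worked-example
arithmetic, a depth-4 phantom recovery run at 0.5 mm/192³, the FWHM
annulus check, the statistics oracles, and the determinism check) and
writes a JSON summary; see the README for invocation.
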