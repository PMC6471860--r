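# airwayvol

Quantitative chest-CT analysis of the **airway-tree-to-lung-volume ratio**
and companion COPD imaging biomarkers, for researchers who want a fully
scripted, phantom-validated alternative to commercial airway software.

In COPD the airway tree shrinks while the lung hyperinflates, and the two
changes interact through parenchymal tethering of the airway wall.  The
core index here is the airway volume percent,

```
AWV% = 100 · AWV / rLV
```

with AWV the lumen volume (ml) of the segmented airway tree in the right
upper + right middle–lower lobes and rLV the right lung volume (ml).  The
package computes, per subject:

* **AWV, rLV, AWV%** — iterative-threshold region growing of the airway
  tree with leakage rollback; lung segmentation with left/right split.
* **TAC** (total airway count) — topology-preserving 3-D skeletonization,
  branch-graph construction with spur pruning, lobar subtree labelling.
* **Ai, WA, WA%** — full-width-half-maximum wall/lumen measurement on
  cross-sections orthogonal to the centerline;
  `WA% = 100·WA/(Ai + WA)`.
* **LAV%** — fraction of lung voxels strictly below −950 HU, and CT-TLV.
* **Size-normalized indices** — AWV/pTLC, rLV/pTLC, Ai/(pTLC)^(2/3),
  Ai/(rLV)^(2/3); GOLD grade; CAT ≥ 10 symptomatic flag.

A **digital chest phantom** (bifurcating cylinder tree with analytic
ground truth, inside ellipsoidal lungs with exact emphysema fractions) and
a **simulated cohort generator** (multivariate-normal CT indices with
known standardized effects on %FEV1 and RV/TLC) make every stage testable
without patient data.  A statistics layer provides Pearson correlations,
standardized-β multiple regression with VIFs, Welch/pooled group
comparisons and one-way ANOVA across GOLD grades.

## Worked example

```r
library(airwayvol)

tree <- build_tree_spec(depth = 4)                    # 15-branch tree
spec <- phantom_spec(shape = c(192, 192, 192),
                     spacing = c(0.5, 0.5, 0.5), blur_sigma_mm = 0)
ph <- rasterize_phantom(tree, spec)

metrics <- run_subject(ph$ct, pipeline_config(measure_fwhm = FALSE))
metrics
#> <subject_metrics> AWV 2.50 ml | rLV 170 ml | AWV% 1.470% | TAC 14 | LAV% 0.0%

analytic_truth(tree)$subtree_volume_ml                # per-lobe truth (ml)
#> [1] 1.423361 1.423361
```

`AWV 2.50 ml` is the voxel volume of lumen assigned to the two lobar
subtrees (cylinder-model truth 2.85 ml; the −12% difference is junction
overlap plus junction voxels assigned to the trachea, within the 15%
recovery tolerance), `TAC 14` matches the 15 generated branches minus the
trachea exactly, and `AWV% = 100·2.50/170`.  On the
printed two-case example from the source cohort the same arithmetic gives
`awv_percent(18, 2519) = 0.7146` and `awv_percent(9, 2998) = 0.3002` — the
severely obstructed case has the markedly lower AWV% despite the larger
lung.

For cohort-level statistics:

```r
d <- simulate_cohort(n = 147, n_symptomatic = 81, seed = 1)
cohort_summary(d)                       # Table-1-style mean ± SD, n (%)
fit_standardized_ols(d, "pct_fev1",
                     c("lav_percent", "wa_percent", "tac", "awv_percent"))
```

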