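---
title: "Quantifying perivascular spaces on T2/FLAIR MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perivascular spaces on T2/FLAIR MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Enlarged perivascular spaces (PVS) — fluid-filled sheaths around penetrating
brain vessels, visible as thin bright tubules on T2-weighted MRI — are an
established imaging marker of cerebral small vessel disease (SVD). `pvsmap`
implements a complete, reproducible pipeline for their computational
quantification: multiscale Frangi vesselness filtering of co-registered
T2/FLAIR volumes, region-aware thresholding, small-cluster removal and
lesion exclusion, regional fractional-volume metrics including the WM/BG-PVS
ratio, and the statistical layer used to relate PVS burden to clinical and
radiological covariates. Because patient MRI from such cohorts is rarely
shareable, the package also contains a synthetic phantom generator with
exact ground truth; every stage of the pipeline is validated against it.

This vignette records the model, the tunable parameters, the design
decisions taken where the method is genuinely open, and what the phantom
validation does and does not establish.

## Vesselness filtering

The core operator scores each voxel for "tubularity" from the eigenvalues
of the scale-normalized Gaussian-derivative Hessian. At smoothing scale
$\sigma$ (mm), let $|\lambda_1|\le|\lambda_2|\le|\lambda_3|$ be the
eigenvalues of $\sigma^2 \, \nabla^2 (G_\sigma * I)$. For bright tubes the
response is zero wherever $\lambda_2 > 0$ or $\lambda_3 \ge 0$, and
otherwise

$$
V = \left(1 - e^{-R_A^2/2\alpha^2}\right)\,
    e^{-R_B^2/2\beta^2}\,
    \left(1 - e^{-S^2/2c^2}\right),
$$

with $R_A = |\lambda_2|/|\lambda_3|$ (line vs. plate),
$R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$ (blobness) and
$S = \sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}$ (structureness). The
per-voxel maximum over an ascending scale list gives the final map, with
the argmax scale recorded.

Parameter choices, all exposed in `frangi_params()`:

* **`alpha = 0.5`, `beta = 0.5`** — the conventional defaults for this
  filter family.
* **`c = "auto"`** — half the maximum Frobenius norm $S$ over the volume at
  each scale, the usual data-driven choice when no constant is given. Note
  one degeneracy: on an image containing a *single* structure, the peak
  response then has the same structureness factor at every scale, so the
  argmax scale carries no information; with realistically cluttered images
  (or a fixed `c`) scale selection behaves normally.
* **Scales `{0.5, 0.9, 1.4, 2.0}` mm** — from sub-voxel tubules to the
  conventional 3 mm PVS diameter ceiling, on a 0.9 mm isotropic grid.
* **Polarity** — PVS follow CSF signal: bright on T2 (`bright`), dark on
  FLAIR (`dark`, implemented by negating the input).
* **Scale normalization** — the Hessian is multiplied by $\sigma^2$
  (second-order normalization) so responses are comparable across scales.
* **Boundaries** — reflective padding, avoiding spurious rim responses at
  the edge of the field of view.

Numerics: Gaussian derivative kernels are sampled analytically, truncated
at $5\sigma$, with the second-derivative kernel corrected to zero DC gain so
constant images produce exactly zero response. Eigenvalues of the symmetric
$3\times3$ Hessians come from the vectorized trigonometric closed form,
followed by two clamped Newton steps on the characteristic polynomial
(the trigonometric form alone loses about $10^{-7}$ relative accuracy near
degenerate pairs; unclamped Newton would diverge *at* them). Voxels whose
whole Hessian is at numerical noise level ($S < 10^{-12}$) are treated as
structureless: the ratio terms of $V$ are scale-free and would otherwise
amplify rounding noise.

## Segmentation

The stage order is fixed: **combine → threshold → exclude → cluster-filter**.

1. **Dual-sequence combination.** Outside the WMH mask the T2 vesselness
   passes through unchanged. Inside WMHs — where T2 alone produces false
   positives — the voxelwise **minimum** of the bright-T2 and dark-FLAIR
   responses is used: both sequences must agree before a voxel can become
   PVS. The minimum is the most false-positive-averse fuzzy conjunction.
2. **Thresholding** applies `threshold_nawm` outside and `threshold_wmh`
   inside the WMH mask, restricted to the quantification regions (white
   matter, basal ganglia, brainstem). Free CSF has no PVS threshold:
   perivascular spaces are by definition intra-tissue, and on phantoms an
   ICV-wide threshold floods the mask with bright tubular-looking CSF edges
   (Dice 0.09 vs. 0.99 with the tissue restriction).
3. **Lesion exclusion** removes lacunes and the subacute stroke cavity
   *before* cluster filtering, so lesion remnants cannot prop up
   sub-threshold clusters.
4. **Cluster filtering** removes connected components of
   `min_cluster_voxels` (default 5) or fewer voxels — 3.65 mm³ at 0.9 mm
   isotropic — which are overwhelmingly noise. Components are computed
   under 26-connectivity by default so obliquely oriented tubes stay
   connected; 6 and 18 are available.

**Thresholds.** The default cutoffs (`0.05` in normal-appearing tissue,
`0.035` inside WMHs) were calibrated once on phantom sweeps: across
noiseless and noisy (σ = 2) phantoms, thresholds in 0.05–0.10 gave Dice
0.94–0.99 against the true tube masks, with 0.05 minimizing the fractional
volume error (within a few percent) while the cluster filter absorbed the
extra noise clusters it admits. The package also provides
`calibrate_threshold()`, which mirrors calibration against a visual PVS
rating: each candidate threshold is applied cohort-wide and the candidate
maximizing the Spearman correlation between resulting fractional volumes
and the scores is chosen, ties broken toward the higher (more conservative)
threshold. Rank-based calibration fixes the *ordering*, not absolute
volumes, and is only well-posed when burden differences between subjects
exceed segmentation error.

## Regional quantification

For each region $R$ (WM, BG, BS) the **fractional PVS volume** is
$100 \cdot |M \cap R| / |R|$ percent, computed in voxel counts. The
**WM/BG-PVS ratio** `frac_wm / frac_bg` contrasts lobar against deep PVS
burden; it is undefined (recorded missing, with a warning) when the BG
fraction is zero. WMH burden is normalized as $100\cdot|WMH|/|ICV|$.
Design details: region denominators include WMH areas, so PVS detected
inside WMHs count toward the WM fraction; clusters straddling a boundary
are counted in the region holding the majority of their voxels, ties going
to WM (the larger region).

## The statistical layer

* **Correlations** (`pvs_correlations()`): Pearson for the inter-regional
  fractional volumes, with $R^2$ reported as $r^2$ (the simple-regression
  coefficient of determination); Spearman for ordinal measures such as
  visual scores. Missingness is handled pairwise.
* **Transformation ladder** (`select_transformation()`): nine candidates
  (cubic, square, identity, square root, logarithmic, 1/square root,
  inverse, 1/square, 1/cubic) applied to each region's outcome; normality
  scored by the Shapiro–Wilk $W$; candidates aggregated by the **minimum
  $W$ across the three regions** (the worst region governs, so one region
  cannot drag the cohort onto a transformation that ruins another); any
  candidate producing a non-finite value (log or inverse of zero) is
  disqualified. PVS fractional volumes are right-skewed and
  multiplicative, so the ladder lands on the logarithm in practice.
* **Regressions** (`fit_models()`, `regression_table()`): one OLS fit per
  regressor on the transformed outcome, unadjusted
  (`outcome ~ regressor`) and adjusted
  (`outcome ~ regressor + age + sex + hypertension`). When the regressor
  is itself a covariate its adjusted row is reported from the
  covariates-only model, the convention of adjusted-model tables. Binary
  encodings: female = 1, hypertension = 1. Each regressor is tested
  marginally, two-sided at α = 0.05, with **no multiple-testing
  correction** — matching standard practice for this analysis, so p-values
  are comparable with published tables.
* **Quartile tests** (`quartile_tests()`): subjects binned by type-7
  quantiles of a PVS measure (boundary values to the lower bin; bins
  emptied by ties merged downward with a warning); one-way ANOVA for
  continuous variables, Kruskal–Wallis for ordinal or skewed ones.

## The phantom and cohort generators

`generate_phantom()` builds, deterministically from a seed:

* an atlas — ICV ball, thick white-matter shell, paired basal-ganglia
  ellipsoids, inferior brainstem cylinder — topologically similar to
  anatomy and trivially synthesizable;
* PVS as **capsules** (cylinders with hemispherical caps) of uniformly
  random orientation, radius 0.5–1.5 mm by default (the ≤ 3 mm convention
  for PVS diameter), rasterized by voxel-center inclusion, each tube wholly
  inside its region — so the per-region true fractional volumes are exact;
* WMH blobs (FLAIR-hyperintense, clipped to WM), lacune and stroke
  cavities;
* T2 and FLAIR renderings: per-tissue mean intensities (PVS bright on T2,
  dark on FLAIR; WMH bright on FLAIR) with precedence stroke > lacune >
  PVS > WMH > tissue, plus additive Gaussian noise (σ = 2 on tissue
  contrasts of 35–90). Rician noise is available behind a flag, but the
  segmentation operates far above the noise floor where the two coincide;
  no bias field, motion or partial-volume effects are simulated.

Default tube densities (expected counts 12/8/2 in WM/BG/BS) are chosen for
tube visibility in the scaled-down 64³ regions; phantom fractional volumes
are therefore phantom-scale, not cohort-scale.

`generate_cohort_table()` draws covariates with the marginal structure of
an elderly SVD cohort (mean age 70, 27% female, 66% hypertensive,
right-skewed lacune/microbleed counts and WMH load, sleep scores PSQI/ESS)
and generates latent regional PVS burdens from a linear model on the log
scale, so burdens are log-normal with means near 4.0% (BG), 1.1% (WM) and
0.6% (BS). Residual noise has a **shared** component across regions
(SD 0.30, common vascular burden; it also induces the strong inter-regional
correlation of PVS loads) and an **independent** per-region component
(SD 0.08). The WM/BG ratio cancels the shared part — this is exactly why
ratio models can expose small differential effects. Default planted
effects follow the SVD pattern the pipeline is designed to detect: BG
driven by age, hypertension, lacunes, microbleeds and WMH load; WM by
lacunes (plus the shared age/hypertension terms) with a small positive
PSQI slope (0.005 per point). A power calculation fixes these choices: with
$n = 500$, PSQI SD ≈ 4.4 and the lacune differential effect contributing
SD ≈ 0.22 to the ratio, the PSQI t-statistic is ≈ 1.9 per region-level
model but ≈ 4 on replicate averages of the ratio — detectable on the
ratio, sub-threshold per region, which is the qualitative signature the
effect structure is meant to reproduce. Because the log-ratio is exactly
log(WM) − log(BG), any planted ratio effect necessarily appears in a
region model; a star pattern holding *exactly* is unattainable in a
coherent generative model, and tests therefore assert planted effects
significant and a disjoint null set quiet.

One caveat: with the small independent noise needed for ratio power, the
synthetic inter-regional correlations are higher than real cohorts
typically show. Passing tests demonstrate correctness of the machinery
under a known generative model, not segmentation accuracy on clinical MRI
— real acquisitions add partial voluming, bias fields and anatomy the
phantom deliberately omits.

## Determinism and problem sizes

Identical specifications (including seeds) give bit-identical volumes,
masks, tables and manifests; `run_pipeline()` records md5 checksums of
every written file. The validation suite uses 64³ phantoms (0.9 mm
isotropic), cohorts of n = 500 with 10–100 replicates for statistical
properties, and 200 null replicates for type-I calibration — sizes at
which every property tested is stable while the whole suite stays fast.
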