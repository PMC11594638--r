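# pvsmap

Computational quantification of enlarged **perivascular spaces (PVS)** on
co-registered 3D T2-weighted and FLAIR MRI, with the statistical analysis
layer used to relate regional PVS burden to clinical and radiological
markers of cerebral small vessel disease (SVD).

Enlarged PVS — thin, fluid-filled tubules around penetrating vessels,
bright on T2 and dark on FLAIR — are an SVD marker whose regional pattern
(lobar white matter vs. basal ganglia vs. brainstem) may carry distinct
information about vascular risk and brain fluid clearance. `pvsmap` is
aimed at neuroimaging researchers who want that quantification as a tested,
reproducible pipeline rather than a chain of one-off scripts.

## What it computes

1. **Vesselness**: multiscale Frangi filtering. At scale σ, with
   `|λ1| ≤ |λ2| ≤ |λ3|` the eigenvalues of the scale-normalized Gaussian
   Hessian `σ² ∇²(G_σ * I)`, the bright-tube response is 0 if `λ2 > 0` or
   `λ3 ≥ 0`, else

   `V = (1 − exp(−R_A²/2α²)) · exp(−R_B²/2β²) · (1 − exp(−S²/2c²))`

   with `R_A = |λ2|/|λ3|`, `R_B = |λ1|/√(|λ2 λ3|)`,
   `S = √(λ1²+λ2²+λ3²)`; maximized over scales.
2. **Segmentation**: T2 vesselness in normal-appearing tissue; inside WMHs
   the voxelwise *minimum* of T2 (bright) and FLAIR (dark-tube) responses,
   so both sequences must agree; per-compartment thresholds; lacune/stroke
   exclusion; removal of clusters of ≤ 5 voxels (3.65 mm³ at 0.9 mm
   isotropic).
3. **Metrics**: fractional PVS volume (%) per region (WM, BG, BS), the
   WM/BG-PVS ratio, WMH/ICV (%), per-region cluster counts.
4. **Statistics**: Pearson/Spearman correlation matrices (R² = r²), a
   nine-candidate normality transformation ladder scored by Shapiro–Wilk W
   (minimum across regions), unadjusted and age/sex/hypertension-adjusted
   linear regressions, quartile ANOVA / Kruskal–Wallis tests.
5. **Phantoms**: synthetic T2/FLAIR volumes with capsule-shaped PVS of
   exact known volume, WMH/lacune/stroke lesions, and a clinical covariate
   generator with configurable planted effects — the ground truth every
   stage is validated against.

See `vignettes/pvs-quantification.Rmd` for the full methods account.

## Worked example

```r
library(pvsmap)

# a noiseless phantom subject with known ground truth
spec <- phantom_spec(noise_sigma = 0, seed = 11, tube_radius_mm_range = c(0.9, 1.5))
ph <- generate_phantom(spec)

v_t2    <- frangi_filter(ph$t2, frangi_params())$values
v_flair <- frangi_filter(ph$flair, frangi_params(polarity = "dark"))$values
seg <- segment_pvs(v_t2, v_flair, ph$atlas, ph$wmh, ph$lacune, ph$stroke)

compute_metrics(seg, ph$atlas, ph$wmh, subject_id = "phantom-11")
#>   subject_id frac_wm frac_bg frac_bs wm_bg_ratio wmh_icv_pct n_clusters_wm
#> 1 phantom-11   0.597    9.55    5.88      0.0624       0.601             4
round(ph$truth$per_region_true_fraction, 3)
#>    wm    bg    bs
#> 0.574 9.663 5.875
dice_overlap(seg$mask, ph$truth$pvs_mask)
#> [1] 0.978
```

The segmented fractional volumes (0.60 / 9.55 / 5.88 %) sit within a few
percent of the exact truth (0.57 / 9.66 / 5.88 %), with Dice 0.98 against
the true tube mask.

On the statistics side, a synthetic cohort with planted effects:

```r
coh <- generate_cohort_table(500, effect_config(), seed = 1)
select_transformation(list(bg = coh$frac_bg, wm = coh$frac_wm, bs = coh$frac_bs))$chosen
#> [1] "logarithmic"
fit_models(coh, "frac_wm", "lacune_count", adjust = TRUE,
           transformation = "logarithmic")
#>   outcome    regressor  beta      se  p_value r2_pct adjusted   n degenerate
#> 1 frac_wm lacune_count 0.121 0.00708 9.25e-52   55.4     TRUE 500      FALSE
```

The ladder picks the logarithm (burdens are log-normal by construction) and
the adjusted model recovers the planted lacune slope (0.117) within one
standard error.

A thin command-line front end lives at `inst/cli/pvsmap`
(`run`, `simulate`, `vesselness`, `segment` subcommands over YAML configs
and NIfTI volumes); `run_pipeline()` is the same entry point from R.

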