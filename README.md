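# volcurve

Nonparametric age–volume curves for biomarker-stratified brain-aging
studies.

Cross-sectional "normative" brain-aging results are usually computed from
cohorts of cognitively normal adults — but cognitively normal is not
biomarker-negative. A fraction of such cohorts carries preclinical
Alzheimer's pathology (abnormal CSF amyloid/tau) or a substantial vascular
burden (white-matter hyperintensities, microbleeds, stroke history), and
their regional atrophy can distort the apparent relationship between age
and brain volume. `volcurve` implements a reusable pipeline for
quantifying that distortion:

1. **A/T/N/V stratification.** Each subject is classified on four binary
   axes from CSF and radiological markers — A (amyloid): Aβ42 < 1030 pg/mL
   or p-tau/Aβ42 > 0.023; T (tau): p-tau > 27 pg/mL; N (neurodegeneration):
   t-tau > 300 pg/mL; V (vascular): Fazekas > 1, more than 3 microbleeds,
   or stroke history — and assigned to one of five study groups (N, AD, V,
   AV, OP); the ambiguous A−/T+/V+ profile is excluded. Inclusion requires
   global CDR 0, passing volumetric QC, no radiological exclusion, age ≥ 50.
2. **Normalization.** Regional volumes are divided by total intracranial
   volume and z-scored per region on the full included cohort; subjects
   with any |z| > 4 are dropped.
3. **Volume curves.** For each region × group, the mean volume at each age
   is estimated by Nadaraya–Watson kernel regression,
   m̂(a) = Σᵢ K((a−ageᵢ)/h) zᵢ / Σᵢ K((a−ageᵢ)/h), K(u) = exp(−u²/2),
   with the bandwidth h chosen from {5, 10, 15} years by 5-fold
   cross-validated MSE. The curve and its pointwise SD are the mean and SD
   of 100 bootstrap replicate fits, evaluated on an integer-year grid
   restricted to ages where the group has at least 5 subjects per 2-year
   window.
4. **Curve comparison.** Two groups are compared per region by the area
   between their curves over the overlapping age range (trapezoid rule,
   1-year resolution, z·years) and a chi-squared statistic
   χ² = Σⱼ dⱼ²/(sd²ₐⱼ + sd²ᵦⱼ) referred to a moment-matched (effective-df)
   chi-squared null that accounts for the strong correlation smoothing
   induces between grid points. P-values are Bonferroni-adjusted over the
   regions of a comparison; significance is called at adjusted p < 0.01.

Because the motivating clinical dataset is access-restricted, the package
ships a synthetic-cohort generator (`generate_cohort()`) that reproduces
the study's structure — five groups of 782/178/212/118/90 subjects with
the motivating cohort's per-group age distributions, biomarkers consistent with each
group's definition by construction, and region volumes following known
piecewise-linear z-trajectories with configurable group-specific atrophy
accelerations — so every stage is testable against ground truth.

## Worked example

```r
library(volcurve)

cohort <- generate_cohort(synthetic_config(), seed = 42)   # 1,380 subjects
strat  <- stratify_cohort(apply_inclusion_filters(cohort)$kept)
strat$sizes
#>   N  AD   V  AV  OP
#> 782 178 212 118  90

nc  <- remove_outliers(normalize_volumes(strat$cohort))
cmp <- compare_groups(nc, "N", "AD", settings = comparison_settings(seed = 42))
cmp
#> Curve comparison N vs AD: 10 regions, 5 significant (adj. p < 0.01)
#>  region_code    area     chi2    df     p_raw     p_adj significant
#>       LRBFBV 13.2428 987.5155 2.095 3.633e-20 3.633e-19        TRUE
#>       LLAMYG 10.0207 593.8493 2.103 1.972e-12 1.972e-11        TRUE
#>      LRENTAV  9.9411 572.9421 1.865 6.338e-11 6.338e-10        TRUE
#>      LLENTAV  9.7372 522.4377 1.983 1.600e-10 1.600e-09        TRUE
#>       LRAMYG  8.9392 400.8648 1.945 3.962e-08 3.962e-07        TRUE
#>          LVV  3.0374  90.3182 1.402 3.349e-02 3.349e-01       FALSE
#>  ...
```

The five regions called significant are exactly the five the default
generator accelerates in the AD group (entorhinal areas, amygdalas, right
basal forebrain); the `area` column is the effect size in z·years over the
shared age range, and `df` is the effective degrees of freedom after
correcting for inter-age correlation of the smoothed curves.

A single fitted curve is a first-class object:

```r
idx <- nc$subjects$group == "N"
rng <- compute_age_range(nc$subjects$age[idx])   # ages with >= 5 subjects / 2y
fit <- volume_curve(nc$subjects$age[idx], nc$z[idx, "LLENTAV"], rng,
                    seed = 42, region_code = "LLENTAV", group = "N")
fit
#> Volume curve LLENTAV [N]: ages 50-79, bandwidth 5 y, 782 subjects, 100 bootstrap replicates
#>   z at endpoints: 0.557 (age 50) -> -0.122 (age 79)
plot(fit)                       # curve with the +-2 SD bootstrap band
predict(fit, ages = 65.5)       # interpolated curve value
```

`run_pipeline(run_config(...))` chains every stage (including
gender-stratified reruns with `gender = "each"`) and writes `curves.csv`,
`comparisons.csv`, `ranking_top10.csv`, `significant_regions.csv`,
`rejections.csv` and a `manifest.yaml` from which
`run_from_manifest()` reproduces the run byte-identically. A thin CLI with
`simulate` / `run` / `report` subcommands is in `inst/cli/volcurve.R`.

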