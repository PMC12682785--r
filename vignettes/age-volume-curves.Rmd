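---
title: "Methods: biomarker-stratified age-volume curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker-stratified age-volume curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volcurve)
```

## The question and the estimand

In a cohort of cognitively unimpaired adults aged 50+, some participants
already carry preclinical Alzheimer's pathology (abnormal CSF amyloid or
tau) or a substantial cerebrovascular burden. `volcurve` quantifies how
much these participants bend the cross-sectional association between age
and regional brain volume. The estimand, per brain region and subject
group, is the "volume curve": the mean TIV-normalized, z-scored regional
volume as a function of age, estimated nonparametrically. Differences
between two groups' curves are summarized by the area between them on
their shared age range and tested with a chi-squared statistic.

Everything is cross-sectional: a curve describes how *cohorts of
different ages* differ, not how an individual's brain changes over time.

## Stratification

Four binary axes are thresholded from CSF and radiological markers, with
strict inequalities throughout (a value exactly at a threshold is
negative):

| axis | positive iff | units |
|------|--------------|-------|
| A (amyloid) | Aβ42 < 1030 **or** p-tau/Aβ42 > 0.023 | pg/mL |
| T (tau) | p-tau > 27 | pg/mL |
| N (neurodegeneration) | t-tau > 300 | pg/mL |
| V (vascular) | Fazekas > 1 **or** microbleeds > 3 **or** stroke history | — |

Because Fazekas scores and microbleed counts are integers, "Fazekas ≥ 2"
and "> 1" (likewise "≥ 4" and "> 3" microbleeds) are the same rule; the
strict-integer form is implemented. The six labels partition the 16
A/T/N/V combinations: AD = A+V−, AV = A+V+, V = A−V+T−, EXCLUDED =
A−V+T+ (an ambiguous mixed profile), OP = A−V− with T+ or N+, and N =
all-negative. Exclusion of the ambiguous profile is applied once, after
the inclusion filters, as a single order-independent rule. Records with
missing or non-positive Aβ42 (the ratio is undefined), or missing
tau/vascular readings, are rejected with a machine-readable reason code
rather than imputed — CSF availability is an inclusion criterion of the
design, and there is no principled fill-in for a thresholded marker.

## Normalization and outliers

Each regional volume is divided by the subject's total intracranial
volume and z-scored per region with the n−1 sample SD. The z-scale is
estimated **once on the full included cohort** and reused for subsets
(groups; genders only when analyzing the pooled run): cross-group area
comparisons are only meaningful if both curves live on one scale. In
gender-stratified reruns the scale is recomputed within each gender
subset, treating each rerun as an independent experiment on its own
population.

Outliers are removed in a single pass: any subject with |z| > 4 in any
analyzed region is dropped, and z-scores are *not* recomputed afterwards,
so the scale stays anchored to the full cohort. The threshold 4 is a
conservative conventional choice (tail mass ≈ 6e−5 per observation under
normality) and is configurable (`z_limit`).

## Reliable age ranges

Curve estimates at ages where a group is sparse are unstable. A group's
reliable range is computed from integer-year sliding windows [a, a+2): a
window is dense if it holds at least 5 subjects, and the range is the
longest contiguous run of dense windows (ties resolved toward the younger
end, making the rule deterministic). Comparisons are restricted to the
intersection of the two groups' ranges. `min_count = 5` and `window = 2`
years are the defaults and match the density rule of the motivating
study.

## Curve estimation

The Nadaraya–Watson estimator with a Gaussian kernel K(u) = exp(−u²/2)
is used:

$$\hat m(a) = \frac{\sum_i K\!\left(\frac{a - \mathrm{age}_i}{h}\right) z_i}
                   {\sum_i K\!\left(\frac{a - \mathrm{age}_i}{h}\right)}.$$

The Gaussian kernel is the common default and never produces zero weight
inside the data range, which matters because the evaluation grid (integer
years over the group's reliable range) can extend a few years beyond the
densest data. Estimates are convex combinations of the observations, so
they always lie within the observed z-range, and as h → ∞ the curve
flattens to the global mean — both properties are asserted in the tests.

**Bandwidth.** h is selected per region × group from candidates {5, 10,
15} years by 5-fold cross-validated mean squared prediction error (folds
assigned by a seeded shuffle into near-equal blocks; CV MSE is the mean
over folds of the mean squared held-out error). Ties — which occur
exactly for degenerate (constant) responses — break toward the smallest
candidate, with a tiny relative tolerance so floating-point noise cannot
turn an exact tie into an arbitrary winner. Selection happens **once,
before bootstrapping**, and all replicates reuse the selected h: selecting
inside each replicate would multiply cost by the candidate count and make
the replicate curves non-exchangeable (each smoothing a different amount).

**Bootstrap.** 100 replicates resample subjects with replacement to the
original size and refit on the same grid. The reported curve is the
pointwise replicate mean and its uncertainty the pointwise n−1 SD.
Internally a replicate is represented by its resample *count vector*, so
all replicates reduce to two matrix products with the fixed kernel-weight
matrix; the tests verify this is numerically identical to refitting on
explicit resamples. A replicate whose kernel mass underflows to zero at
some grid point is redrawn and counted (`n_redraws`) — practically
unreachable with a Gaussian kernel on a restricted grid. CV folds and
bootstrap draws use seed streams derived independently from the master
seed, so changing the CV seed never perturbs the bootstrap and fits are
bit-reproducible.

## Comparing curves

**Area.** The area between two curves over the overlap [lo, hi] is the
trapezoidal integral of the absolute pointwise difference at one-year
resolution, in z·years. Smoothness of the curves makes finer resolution
pointless.

**Chi-squared test.** The statistic is
χ² = Σⱼ dⱼ²/(sd²ₐⱼ + sd²ᵦⱼ) over the J grid points of the overlap, with
d the difference of curve means and the denominators the pooled bootstrap
variances. Kernel smoothing makes neighbouring grid points strongly
correlated, so referring χ² to a chi-squared distribution with J degrees
of freedom is badly anti-conservative — in the package's null
simulations, with near-perfectly correlated grid points, the nominal-df
test rejected in nearly every family. The default therefore
moment-matches the null of the correlated quadratic form (Satterthwaite):
with R the correlation matrix of the pointwise differences, estimated
from the bootstrap replicates of both curves, χ² is referred to
c·χ²(ν) with c = tr(R²)/J and ν = J²/tr(R²). Both methods coincide for
uncorrelated grids and for a single grid point; the nominal variant
remains available (`chi2_method = "nominal"`). The resulting effective
df is real-valued, typically close to 1–3 for these smooth curves. The
family-level calibration of the default is asserted by a 200-repetition
null simulation in the acceptance tests.

Two caveats are deliberate. First, comparisons against the full cohort
("ALL") include the reference group's own subjects on both sides; the
area remains a valid descriptive effect size, but the test's independence
assumption fails, so such rows are flagged `descriptive`. Second, when
two groups have different age *distributions*, kernel smoothing biases
each curve toward its own group's age mass (the m′f′/f design-bias term),
so a significant difference partially reflects design imbalance as well
as volume differences; this is inherent to comparing Nadaraya–Watson
fits and is shared with the original design.

**Multiplicity.** P-values are Bonferroni-adjusted, family = the regions
within one group-pair comparison, and significance is called at adjusted
p < 0.01. The family is the comparison (not regions × comparisons)
because each group contrast answers a separate scientific question; the
`bonferroni_adjust(p, m)` helper accepts any declared family size.

## The synthetic cohort

The generator emulates the structure of the motivating cohort so the
pipeline can be tested with known ground truth:

* group sizes 782 (N), 178 (AD), 212 (V), 118 (AV), 90 (OP) — 1,380 in
  total — with the motivating cohort's female fractions and per-group, per-gender
  age moments, drawn from normals truncated at 50;
* biomarker values sampled from intervals bounded away from each
  threshold by a 5% relative margin, so boundary conventions can never
  flip a synthetic label, and satisfying each group's A/T/N/V definition
  by construction (free axes drawn at a 25% positivity rate);
* TIV ~ Normal(1450, 130) mL; each regional volume is
  tiv × (ratio_mean + ratio_scale × z) with
  z = baseline + slope·(age−50) + effect + gender offset + N(0, noise_sd),
  noise_sd = 0.5 by default;
* trajectories are piecewise-linear in age: a common baseline decline of
  −0.02 z/year plus group-specific accelerations after an onset age
  (default: −0.03 z/yr after 60 in five medial-temporal/basal-forebrain
  regions for AD, −0.035 for AV, −0.03 in three fronto-opercular/
  subcortical regions for V), echoing the topography reported for these
  profiles. A quadratic term and gender-specific effects are available in
  the config. Piecewise-linear was chosen because it exercises the
  estimator, the bandwidth selection, and the area statistic while
  keeping every target value analytically available via
  `true_mean_curve()`.

What the generator does **not** emulate — and what passing tests
therefore cannot certify about real data: correlation between regions
within subject (regions are independent given age), CSF assay noise and
its correlation structure, non-Gaussian volume noise, QC failures and
radiological exclusions (all synthetic subjects pass), and longitudinal
visits.

## Numerical and reproducibility choices

* All seeded functions save and restore the caller's RNG state; child
  streams are derived from the master seed by a labelled LCG step, so
  every stage is independently reproducible.
* `run_pipeline()` writes a `manifest.yaml` at full floating-point
  precision; `run_from_manifest()` reproduces a run byte-identically.
  Pipeline problem sizes in the shipped tests use reduced group sizes and
  bootstrap counts (the statistical properties under test do not depend
  on them); the acceptance checks run at the study's own 1,380-subject
  scale where the property is about that scale.
* Degenerate inputs fail loudly with the offending entity named: zero
  TIV-ratio variance (a region that cannot be z-scored), all-zero kernel
  mass at a grid point, zero pooled variance in the chi-squared test,
  disjoint age ranges, an empty post-filter cohort.
* The recovery error of a fitted curve against `true_mean_curve()` is
  measured on the generator's latent z scale (mapping the fitted curve
  back through the known affine normalization), because that is the
  scale on which the generator's noise SD and effect sizes are defined;
  the cohort z-score unit is smaller by the cohort's total-variation
  factor and would conflate scale with accuracy.

## Limitations

Nadaraya–Watson with bandwidths of 5–15 years over an age spread of ~25
years is a *heavily smoothed* estimator: curves are attenuated toward
each group's mean age, and boundary estimates lean on one-sided data.
Local-linear (boundary-corrected) regression would reduce this but is
out of scope by design. The chi-squared effective-df correction is a
second-moment approximation certified by simulation, not an exact null.
Covariates (education, lifestyle, comorbidity) are not modelled. All
results on synthetic cohorts inherit the generator's simplifications
listed above.
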