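---
title: "Norm-based subtyping of regional brain atrophy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Norm-based subtyping of regional brain atrophy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adsubtype)
```

## The problem

Not all Alzheimer's disease (AD) patients show the textbook MRI picture of
combined hippocampal and association-cortex atrophy. Because regional brain
volumes also shrink with normal ageing and differ between genders and head
sizes, raw volumes cannot separate disease-related atrophy from these
confounds. This package implements a normative approach: regional volumes
are expressed relative to what is *normal for a person of that age, gender
and head size*, and patients are then sorted into four atrophy subtypes by
a fixed rule set.

The pipeline has five stages:

1. **ICV scaling.** Four regions of interest (ROIs) — bilateral sums of
   hippocampus, middle frontal, superior temporal and inferior parietal
   cortex, in mm³ — are divided by intracranial volume (ICV), giving
   dimensionless normalized volumes.
2. **Normative table.** From a cognitively normal (CN) cohort, the mean and
   SD (n−1 denominator) of each normalized volume are tabulated per
   (age stratum × gender) cell.
3. **Z-profiles.** Each patient's normalized volumes are standardized
   against the matching cell: `z = (ratio − mean) / sd`, yielding
   (Z_H, Z_F, Z_T, Z_P).
4. **Rule-based classification.** With atrophy defined as Z strictly below
   −1.0: hippocampal *and* ≥1 cortical ROI atrophic → **BI** (both
   impaired); hippocampal only → **HA**; ≥1 cortical only → **CA**;
   neither → **BS** (both spared). The four rules partition ℝ⁴.
5. **Group comparisons.** Chi-square tests for categorical baseline
   variables, ANOVA/ANCOVA (education covariate) for continuous ones,
   Kruskal–Wallis and Mann–Whitney tests for the skewed CSF biomarkers,
   and random-intercept linear mixed models for 2-year cognitive
   trajectories.

## Normative machinery

### Overlapping age strata

The default stratification is four overlapping strata with inclusive
bounds — 55–70, 65–80, 70–85, 75–90 years — per gender. Overlap means a CN
subject whose age falls in two intervals contributes to both cells, which
stabilizes cell means and SDs near bin edges at the cost of correlated
neighbouring cells. The exact bounds used by any given normative study are
a reporting detail of that study; here they are a configurable
`strata_spec()`, and the defaults were chosen once as four equal-width
intervals covering 55–90 with 5-year overlaps.

### Which stratum does a patient's Z use?

Overlap is unambiguous for *building* the table but ambiguous for *lookup*.
The rule here: the stratum whose midpoint is nearest the subject's age,
ties resolved to the younger stratum (`assign_stratum()`). This is the
standard resolution in overlapping-cell normative work, it is deterministic,
and it makes the assigned index non-decreasing in age. An alternative —
averaging norms across all containing strata — was rejected because it
blurs the cell provenance of each Z and complicates the self-consistency
property below.

Ages outside the covered range raise an error by default; a `clamp = TRUE`
option reuses the nearest boundary stratum with a warning, because silent
extrapolation of norms is how out-of-range patients get misread.

### Why the simple ratio, not residual regression

ICV correction is `volume / ICV`. Regression-based residualization is a
reasonable alternative in general, but the ratio is the method the
normative table is defined around, it is scale-free (multiplying every
volume and ICV by a common constant leaves every Z unchanged — a tested
invariant), and it keeps the norm table a plain mean/SD object.

### Guard rails

`min_stratum_n` (default 20) rejects norm tables with under-filled cells;
a zero-variance cell is a hard error. Both states produce useless or
infinite Z-scores, so failing early is the only safe behaviour.

A useful identity for testing: when each CN subject contributes to exactly
one cell (non-overlapping strata whose midpoint partition coincides with
the intervals), Z-scoring the CN cohort against its own table must give
per-cell mean 0 and SD 1 to machine precision. The test suite checks this
at 1e−9.

## The classifier

`classify_subtype()` evaluates the rule table with the cortical condition
written as `min(z_f, z_t, z_p) < cutoff` — numerically identical to "at
least 1 of 3 below cutoff" but a single comparison. The inequality is
strict, so a profile sitting exactly at −1.0 everywhere is *both spared*.
Frequencies are reported rounded half-up to one decimal
(`subtype_frequencies()`), matching conventional clinical-table rounding;
with counts (96, 31, 19, 17) of 163 this prints 58.9 / 19.0 / 11.7 /
10.4%.

## The synthetic cohort generator

Real data of this kind are access-controlled, so the generator produces
cohorts carrying the statistical structure the pipeline assumes. It is a
first-class, tested module, and its defaults are fixed study conditions:

| Parameter | Default | Why |
|---|---|---|
| `n_cn`, `n_ad` | 222, 163 | analysed cohort sizes after QC |
| age | uniform on [55, 90] | study recruitment range; group-specific age means are deliberately not force-matched |
| `female_fraction` | 0.48 | CN gender split |
| ICV | ♀ 1.38e6 ± 1.1e5, ♂ 1.55e6 ± 1.2e5 mm³ | plausible values creating a genuine gender/head-size confound for the norm machinery to remove |
| CN ROI trend | linear decline in age with Gaussian residuals | e.g. hippocampal ratio 0.0046 at 55, −1.5e−5/yr, SD 4.5e−4; intercepts/slopes chosen so CN means near 75 sit close to atrophy-spared patient values |
| `subtype_mixture` | 0.589/0.190/0.117/0.104 | reported subtype frequencies |
| `subtype_z_effects` | reported per-subtype mean Z-profiles | effect-size targets |
| CSF | log-normal per group, median/IQR from the reported biomarker table | concentrations are right-skewed; `meanlog = log(median)`, `sdlog = log(q75/q25)/(2Φ⁻¹(0.75))` reproduces both summaries |
| decline slopes | MMSE/yr: BI −2.0, HA −1.4, CA −2.8, BS −0.7 (analogous for the composites) | per-subtype numeric slopes are not published; values chosen once, ordered CA fastest and BS slowest as reported qualitatively |

### Injecting AD effects relative to the empirical norms

AD subjects' normalized volumes are generated as
`cell_mean + z · cell_sd` using the *empirical* norm table (not the
generative truth), with `z ~ N(subtype mean Z, z_noise_sd)`. Because
classification later standardizes against the same cells, the injected z
is recovered exactly and the expected Z-profile of each latent class
equals its configured vector by construction, regardless of sampling noise
in the norm table itself.

### Calibrating the within-subtype dispersion

`z_noise_sd` is the one free dispersion parameter. The published
within-subtype Z SDs (0.57–1.39) cannot be used directly: they describe
profiles *after* the rule set has truncated each class to its own region
of Z-space, so reusing them as generative noise overstates
pre-classification spread and floods the −1.0 boundary with
misclassification. The generator's contract is instead that the expected
*classified* mixture equals the configured mixture, with leakage across
the boundary a small perturbation. Under the noise model the four Z's are
independent normals, so the latent→classified confusion matrix has a
closed form in normal orthant probabilities, exposed as
`subtype_confusion_matrix()`:

```{r}
M <- subtype_confusion_matrix()
round(M, 3)
# expected classified mixture under the default latent mixture
mix <- c(BI = 0.589, HA = 0.190, CA = 0.117, BS = 0.104)
round(drop(mix %*% M), 3)
```

The default `z_noise_sd = 0.35` keeps every diagonal entry ≥ 0.97 and the
expected classified-vs-configured deviation below half a binomial SE at
n = 2000, while leaving misclassification nonzero and concentrated near
the boundary (the HA and CA cortical means sit only 0.8–1.0 above the
cutoff, and remain the dominant leakage paths). Larger dispersions are
available through the configuration; the confusion matrix quantifies their
cost before any simulation is run. The matrix is itself validated against
empirical confusion frequencies in the test suite.

### What the generator does *not* emulate

Scores are exactly linear-Gaussian: no MMSE ceiling/floor truncation, no
practice effects, no informative dropout (missingness is
missing-at-random per visit, default 0), no correlation between atrophy
degree and CSF values within a subtype, and no age–subtype association.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and internally consistent — not that the classifier would achieve
any particular accuracy on real scans, where segmentation error and
norm-cohort mismatch dominate.

## Statistical modules

* **ANOVA/ANCOVA** (`one_way_anova()`, `ancova()`): standard linear-model
  fits; ANCOVA reports the group F with the covariate entered first, and
  falls back to ANOVA with a warning when the covariate is constant. The
  post-hoc procedure is Tukey HSD by default (Bonferroni available): the
  original report says only "post-hoc test", so this is an explicit open
  interpretation, not a reconstruction.
* **Chi-square** (`chi_square_test()`): Pearson, *no* continuity
  correction — the tables here are 2×4, and Yates' correction (a 2×2
  device) would not reproduce the published p-values (0.095 gender, 0.091
  ApoE ε4, both matched by this implementation to ±0.002).
* **Mann–Whitney** (`mann_whitney()`): exact permutation enumeration of
  all C(n₁+n₂, n₁) rank assignments when both samples have ≤ 8
  observations (ties handled through average ranks; two-sided p as the
  probability of a U at least as far from its null mean), otherwise the
  tie-corrected normal approximation without continuity correction. The
  threshold 8 keeps enumeration ≤ 12,870 assignments. Fully tied data give
  p = 1. Whether the original pairwise p-values were
  multiplicity-adjusted is unstated; the default here is unadjusted.
* **Kruskal–Wallis** (`kruskal_wallis()`): tie-corrected H with χ²(k−1)
  p-value; consistent with the asymptotic Mann–Whitney at k = 2 (tested to
  1e−10).
* **Median/IQR** (`median_iqr()`): linear interpolation between order
  statistics (type-7 quantiles), the most common convention.

## The longitudinal mixed model

`fit_lmm()` fits, by REML via `lme4`,

```
outcome ~ subtype * time + education + (1 | subject)
```

with time numeric in years (0, 1, 2), so fixed-effect slopes are annual
change and the reference subtype's slope is the bare time coefficient.
Design choices:

* **Reference level BI** — the largest group, hence the most precise
  reference.
* **Interaction test**: joint Wald χ² on the interaction block from the
  REML fit. A likelihood-ratio test on ML refits is asymptotically
  equivalent; Wald avoids refitting and is standard at these sizes. No
  small-sample denominator-degrees-of-freedom correction is applied — at
  ~160 subjects × 3 visits the χ² reference is adequate, and the null
  simulation in the test suite confirms approximately uniform interaction
  p-values.
* **Random intercepts only**, as specified by the design being mirrored;
  with three visits, random slopes would often be weakly identified
  anyway.
* **Missing visits** are dropped row-wise; subjects with only a baseline
  still inform the intercepts. Singular (zero-variance) fits are allowed:
  on noiseless data the point estimates are exact and their sampling
  variance is genuinely zero.
* `slope_contrasts()` reports all pairwise slope differences with Wald
  normal p-values, additive around cycles by construction.

## Numerical conventions and edge cases

* Percentages round half-away-from-zero to one decimal (not banker's
  rounding).
* Norm tables serialize to CSV with 17 significant digits plus a JSON
  sidecar carrying the stratification, so a write/read round trip is
  bit-lossless.
* Generator functions each derive an independent seed stream from the
  configuration seed (offsets 0–3), so `generate_csf()` output does not
  change when the longitudinal generator is skipped.
* Degenerate inputs fail loudly with classed conditions
  (`adsubtype_config_error`, `adsubtype_range_error`,
  `adsubtype_insufficient_norm_error`, …) naming the offending field or
  cell.

## Problem sizes used in the tests

The suite exercises: norm-table construction at 200–600 CN subjects;
classifier enumeration over the full {−2, 0}⁴ grid plus 500-profile
fuzzing; generator recovery at n_ad = 2000 with a 500-subject norm cohort;
slope recovery at 60 subjects per subtype; a 200-replicate null simulation
for the interaction test; and 1500-replicate type-I-error checks for the
ANOVA. These sizes give stable Monte-Carlo margins (3·SE bands) while
keeping the default test run around half a minute.

## Known limitations

* The default stratum bounds and the lookup rule are reasonable choices,
  not reconstructions of any particular study's unpublished normative
  table; with other bounds the classifier output for boundary-age
  subjects changes.
* The rule-based classifier has no notion of measurement error in the
  volumes; Z within ±ε of the cutoff is classified as confidently as any
  other value.
* The LMM assumes linear mean trajectories over 2 years; with only three
  visits this is close to saturated, but curvature in real decline is
  absorbed into the residual.
* CSF draws are independent across markers within subject apart from the
  shared denominators in the ratio variables; real tau/Aβ correlations
  are stronger.
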