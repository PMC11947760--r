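---
title: "Matched-bootstrap group contrasts for WMH burden: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched-bootstrap group contrasts for WMH burden: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhboot)
```

This vignette is the package's account of its statistical machinery: the
generative model behind the synthetic cohorts, the matching design and the
variance trade-offs that shaped it, the model fitters, the percentile
aggregation, and the numerical conventions. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The analysis in one paragraph

The scientific question is whether white matter hypointensity (WMH) burden
differs between demographic groups after composition imbalance is removed,
and how much of any difference is carried by vascular risk factors. The
procedure: repeatedly subsample the larger (reference) group to the smaller
(target) group's size, matched on age, sex, education and diagnosis; fit a
linear model of WMH burden on each balanced sample; and summarise the group
coefficient across iterations by its median effect size, median
t-statistic, and 95% / 99.5% percentile confidence intervals of the
t-statistic. Comparing runs with and without diabetes, hypertension and BMI
as covariates (on identical match plans) separates direct from
vascular-mediated group differences.

## 2. The synthetic cohort generator

Real cohorts of this kind are access-restricted, so the generator
(`cohort_baseline()`, `cohort_longitudinal()`) emulates their *statistical*
structure — nothing more. Its two ingredients:

**Group profiles.** Per group: normal age, education (truncated at 0 years)
and BMI (truncated at 12 kg/m²) margins; Bernoulli sex, hypertension and
diabetes; categorical NC/MCI/AD diagnosis. The default profiles
(`clinical_cohort_profiles()`, `mri_cohort_profiles()`) reproduce the
published descriptive margins of the NACC clinical sample (7132 White, 892
Black, 283 Asian, 661 Hispanic participants) and its MRI subset
(1876/260/55/207). Truncation points prevent impossible values without
materially changing the means.

**Outcome model.** On the scale `y = log(total WMH volume in mm³ + 1)`:

y = intercept + β_group[g] + β_age·age + β_edu·edu + β_male·male +
β_MCI + β_AD + β_htn·HTN + β_dm·DM + β_bmi·BMI + slope[g]·t + b_i + e_it

with subject intercept `b_i ~ N(0, σ_subject²)` and visit residual
`e_it ~ N(0, σ_resid²)`. Regional volumes are apportioned from the total as
`log(w_r) + y + N(0, 0.1²)` with weights 0.58/0.33/0.05/0.04
(frontal/parietal/temporal/occipital), which keeps regional totals and
orderings consistent with published volumetric ranges. Ordinal severity is
staged from `y` at two cutpoints (lower bound inclusive); severity enters
regressions as numeric 0/1/2, matching the magnitude of published
severity-scale effect sizes.

Default effect sizes were fixed once, before any pipeline run, to encode
the qualitative structure the analysis is designed to detect at plausible
magnitudes: a direct Black–White effect of 0.23 plus a vascular-mediated
path of ≈0.10 on the log scale (so vascular adjustment attenuates but does
not abolish the contrast, mirroring the published 0.33 → 0.25 volumetric
pattern); a negative direct Hispanic effect partially masked by a positive
vascular path; no Asian effect; slower progression for Asian participants
(annual slopes 0.08/0.10/0.02/0.06 for White/Black/Asian/Hispanic). Noise
scales σ_subject = 0.5, σ_resid = 0.6 put the marginal SD of log-volume
near 0.9 and the implied volume range over ~2000 participants at roughly
400–140 000 mm³, consistent with published ranges. The default intercept
5.7 centres log-volume near 8.9.

Default severity cutpoints (8.97, 9.70) are the 52nd and 80th percentiles
of the default latent distribution, giving a ≈52/28/20 low/moderate/
extensive mix. Visit counts are `1 + Poisson(n_visits_mean − 1)` with
`n_visits_mean = 1.87`; inter-visit gaps are normal(455, 160) days floored
at 1 day and converted to years by /365.25. The published follow-up tables
report a mean inter-assessment time of ≈454–455 days (one printed value,
"45276 days", is an evident misprint of ~452.76 and is not used).

Longitudinal extension accepts *any* schema-complete baseline table: the
subject intercept is recovered from the baseline outcome by its conditional
normal distribution given the deviation from the linear predictor
(`b | s ~ N(ρs, ρσ_resid²)`, `ρ = σ_subject²/(σ_subject² + σ_resid²)`), so
follow-up visits share the participant's intercept exactly even when the
baseline was not generated in the same call. As `σ_resid → 0` this
degenerates correctly to constant trajectories under zero slopes.

**Scenario configurations** freeze the three causal structures used for
validation: `config_mediation()` (vascular paths plus a direct effect, at
the clinical group sizes), `config_suppression()` (direct effect set to
minus the analytically expected mediated path `Δhtn·β_htn + Δdm·β_dm +
Δbmi·β_bmi`, so the unadjusted contrast is zero in expectation by
construction), and `config_null()` (identical groups, no effect, at an 8:1
reference:target ratio — the most unfavourable pool ratio among the real
contrasts).

**What the generator does not emulate:** site/scanner effects, spatially
realistic lesion maps, non-linear age effects, informative dropout,
correlated vascular factors, measurement error in covariates. Passing tests
therefore show that the *pipeline* recovers the structure it assumes, not
that the assumed structure exhausts real data.

## 3. The matching design

Each iteration selects a reference subsample of exactly the target group's
size. Two covariate types are treated differently:

* **sex × diagnosis: exact stratification.** Within each of the six cells
  the selected reference count equals the target count — a hard invariant.
  A cell with fewer candidates than targets raises an error naming the
  cell; `replace_infeasible = TRUE` instead fills the cell by sampling with
  replacement, with a warning.
* **age, education: randomised k-nearest-neighbour.** Both variables are
  standardised by the reference-pool SDs. Targets are visited in a
  shuffled order; each draws uniformly at random among its `k_nearest`
  (default 10) nearest still-available candidates.

The uniform draw among the k nearest is the load-bearing choice, and it was
made on variance grounds at design time. A deterministic greedy
nearest-neighbour rule (recovered here by `k_nearest = 1`) selects nearly
the same reference participants in every iteration, because the only
randomness left is the target order. The across-iteration spread of the
t-statistic then collapses — in design experiments under a null generator,
the 95% percentile interval narrowed to ≈0.5 t-units against ≈2.4 for the
randomised rule — and a percentile interval built from a collapsed
distribution excludes zero constantly, producing a meaningless
significance rule. (Published intervals for analyses of this design are
≈2.5 t-units wide, consistent with genuinely random subsampling.) The
k-nearest draw bounds the fraction of reference-side noise shared across
iterations at ≈1/k while keeping every matched pair among the closest
available candidates; measured per-candidate selection probabilities are
close to the uniform-subsampling ideal. Matching quality is monitored, not
assumed: `balance_diagnostics()` reports standardised mean differences
(difference of means over the pooled SD) for age and education and raw
proportion differences for sex and each diagnosis level, pre- and
post-match, and the test suite requires post-match |SMD| < 0.1 on cohorts
at the published sizes.

A structural limitation worth stating plainly: the target group is fixed
across iterations, so the median-over-iterations t-statistic retains the
target group's sampling noise. Its variance is therefore bounded below by
(target-side variance)/(total variance) = 1/2 under 1:1 matching, i.e.
E|median t| ≳ 0.56 under a true null for *any* matched-resampling rule,
and the 99.5% percentile interval estimated from 100 iterations
under-covers slightly because its bounds interpolate the most extreme
order statistics. The null-calibration figures reported by
`scripts/acceptance.R` (mean |median t| ≈ 0.6–0.7, 99.5%-CI exclusion
≈ 4–9% across null cohorts) sit at this floor, not above it; users should read
isolated |median t| values below ~1 as noise, and rely on the percentile
intervals plus replicate cohorts rather than the median alone.

## 4. Model fitting

`build_design()` codes the design explicitly: reference-coded group
indicator, male = 1, diagnosis dummies against NC, time in years
(days/365.25), log outcomes as `log(x + 1)` — the `+1` because occipital
volumes of 0 mm³ occur in real data — and complete-case filtering with a
dropped-row count. Interaction models enter age at the participant's
baseline visit.

Baseline models use QR least squares (`fit_ols()`): classical SEs,
t-statistics on `n − rank` degrees of freedom, two-sided p-values. An
exactly collinear design errors naming the offending columns; a numerically
exact fit sets an `exact_fit` flag rather than reporting near-infinite
t-statistics as inference.

Longitudinal models add a participant random intercept, fitted by REML
(`fit_random_intercept()`). With a single variance ratio
`λ = σ_subject²/σ_resid²`, everything profiles: for fixed λ the fixed
effects are GLS with per-subject Sherman–Morrison inversion
(`V_i⁻¹ = I − λ/(1 + n_i λ) J`), and both variances have closed forms, so
the REML criterion

-2·logL_R(λ) ∝ Σ_i log(1 + n_i λ) + log|XᵀV*⁻¹X| + (n − p)·log(RSS_GLS)

is minimised over log λ by one-dimensional search (`stats::optimize`,
search range log λ ∈ [−14, 10], tolerance 1e-9; the evaluated profile is
retained in the fit object). λ = 0 is compared explicitly so boundary
estimates (zero subject variance) are allowed and flagged; the fit then
equals OLS. Fixed-effect SEs come from the GLS information matrix and
p-values use the normal approximation — no Satterthwaite correction — which
is recorded in the fit metadata (`dof_method = "normal"`). The test suite
checks this fitter three independent ways: the balanced one-way ANOVA
closed form to 1e-6, the boundary reduction to OLS, and agreement with
lme4's REML on an unbalanced longitudinal fit (lme4 is a Suggests-only
test oracle, never the implementation).

Descriptive comparisons use the unequal-variance (Welch) t-test computed
from summary statistics — chosen because it reproduces published
t-statistics from the printed group means and SDs, where the pooled test
does not — and Pearson chi-square without continuity correction.
`harmonize_vascular_columns()` merges the overlapping raw indicator columns
found in multi-freeze cohort exports (any-positive rule; all-missing stays
missing; BMI plausibility range 12–70 kg/m²).

## 5. Resampling and aggregation

Iteration i's seed is a pure function of `(master_seed, i)`
(`iteration_seed()`), so any single iteration can be reproduced without
replaying the run, a longer run extends a shorter one exactly, and two runs
with the same master seed are byte-identical. Percentile intervals use
linear interpolation between order statistics (`quantile` type 7) at
`(1 ± level)/2`; exclusion flags require both bounds to share a strict
sign. Iterations whose fit fails are excluded and counted; more than 5%
failures aborts the run as a sign of systematic infeasibility rather than
noise.

For interaction models the tables of this literature are ambiguous about
whether the group main effect or the group-by-time coefficient is
tabulated (published main-effect and interaction t-values differ), so the
summary carries both: the main effect in the primary fields and the
group-by-time term under `$interaction`.

`compare_adjustment()` runs base and vascular covariate sets on *identical*
per-iteration match plans — paired seeds — so the adjustment effect is not
confounded by resampling noise, and classifies the flag flip (95% level):
significant → null is "attenuated", null → significant is "revealed"
(suppression), otherwise "unchanged". `regional_panel()` fits total plus
four regional outcomes under both covariate sets (10 summaries) on shared
plans per iteration.

## 6. Problem sizes used in validation

The test suite and acceptance script validate at the study's own scales
where that is what is being claimed, and at reduced scales where only the
mechanism is under test: attenuation and suppression recovery run 20
replicate cohorts at the full published group sizes with 200 iterations
each; null calibration runs 200 cohorts of 2400 + 300 participants at 100
iterations; variance-component recovery uses 500 subjects × 3 visits; unit
tests of the machinery use cohorts of a few hundred. Default
`n_iterations = 1000` remains the analysis-scale setting.

## 7. Known limitations

* Random intercepts only — no random slopes; group-specific progression is
  a fixed-effect interaction.
* Ordinal severity is modelled linearly (0/1/2), not by proportional odds;
  this matches the analysis the package reproduces, at the cost of
  treating category gaps as equal.
* Mixed-model p-values are normal-approximation; for the sample sizes this
  package targets (hundreds to thousands of subjects) the approximation is
  benign, but small-sample users should read them cautiously.
* The adjustment comparison is a covariate-adjustment contrast, not a
  formal mediation decomposition: no indirect-effect estimand or CI is
  computed.
* The median-t floor of Section 3 means the pipeline's median t is not a
  calibrated null statistic; the percentile intervals are the inferential
  object.
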