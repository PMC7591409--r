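---
title: "Methods: the frailty index, the mortality-based cutoff, and the falls analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the frailty index, the mortality-based cutoff, and the falls analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtyfalls)
```

`frailtyfalls` implements a deficit-accumulation frailty workflow for
single-age cohorts of older women followed in waves (defaults: ages 75, 80
and 85), centred on recurrent falls as the outcome. This vignette explains
the model and procedure, the parameters that matter, the numerical choices,
what the synthetic-data generator does and does not emulate, and the design
decisions that were genuinely open.

## The frailty index

The index follows the standard deficit-accumulation construction: thirteen
health variables, each scored on [0, 1] where 0 is the healthy state, and
the index is the mean score over non-missing items. Two item kinds exist:

* **Binary items** are dichotomised at a cut-point; the unhealthy side
  (inclusive) scores 1. Which side is unhealthy is declared per item
  (`direction`), never inferred.
* **Continuous items** are min–max rescaled,
  $(V_x - V_\min) / (V_\max - V_\min)$, clamped to [0, 1], with the
  complement taken for items where *lower* values are unhealthy. The
  worked example is the number of steps taken to walk 30 m: range 21–160,
  so 54 steps scores $(54-21)/139 = 0.237$, and fewer steps (longer
  stride, healthier) score closer to 0. Rescaling is invariant to affine
  increasing transforms of the raw scale, which the test suite asserts.

$V_\min$ and $V_\max$ are fixed from the observed cohort range *after
excluding extreme outliers*. The exclusion band is the closed empirical
quantile interval, by default the 0.5th–99.5th percentiles. Quantiles are
computed as order statistics (R's `type = 3`, no interpolation): with an
interpolated definition the band edge can fall between observations and
trim genuine extreme values that are not outliers; with order statistics
the band always lies on observed values, so a single gross outlier is
removed while the true minimum and maximum survive.

**Missing items.** The index is the mean over non-missing items, provided
at least 80% of items (11 of 13) are scored; below that the index is
undefined and the record is flagged and excluded from analyses. The
mean-over-available-items rule is the standard deficit-index convention;
requiring complete data would discard records non-randomly (frailer women
miss more measurements).

**Classification.** Women with index ≥ 0.25 are frail. The boundary is
configurable (`frail_boundary = "gt"` gives strictly greater), because
both conventions appear in practice; ≥ is the default as the majority
usage. The cutoff itself (`cutoff = 0.25`) is a parameter of
`index_config()`, not a constant.

**Quintiles.** Frailty gradients use equal-sized quintiles of the
*analysis subsample* — attendees with valid falls data at the outcome
visit — never of the full baseline cohort, since attrition changes the
distribution. Sizes differ by at most one (remainders go to the lowest
quintiles, so n = 101 gives 21, 20, 20, 20, 20). Ties are broken by
stable input order by default, which preserves the size guarantee; an
alternative `ties = "lower"` assigns boundary-spanning ties to the lower
quintile, which can unbalance sizes and is provided for sensitivity
checks only.

**Comparing two indices.** `compare_indices()` reports the Pearson
correlation over complete pairs plus each index's mean and median. It is
deliberately minimal: the package does not construct any alternative
index, it only compares two supplied vectors.

## The empirical mortality cutoff

The 0.25 threshold is motivated empirically: candidate cutoffs are scanned
in 0.02 increments and, for each candidate $c$, the 10-year mortality among
women with baseline index ≥ c is recorded (`scan_mortality()`). Candidates
supported by fewer than 10 women are marked unstable and excluded. An
alternative mode records the mortality *difference* between the groups at
or above and below the candidate, since "differences in mortality" admits
both readings; `at_or_above` is the default and the mode is recorded on
the scan object.

The "beginning of a steeper slope" is formalised as a continuous
two-segment piecewise-linear least-squares fit with the breakpoint
restricted to the stable candidate grid (`detect_slope_change()`): for
each admissible breakpoint a hinge regression
$y \sim x + \max(x - b, 0)$ is fitted and the breakpoint minimising the
residual sum of squares wins; exact ties go to the smaller cutoff. This is
the simplest reproducible formalisation of a visual knee. A changepoint is
only reported as *distinct* when the upper slope clearly exceeds the
lower: by a factor ≥ 2 when the lower slope is positive, or by ≥ 0.1
mortality per unit index otherwise (the ratio criterion is meaningless at
a flat or negative lower slope). A globally linear curve is flagged as
having no distinct changepoint rather than returning an arbitrary break.

Two numerical facts matter in practice:

* On exact two-segment input the breakpoint is recovered exactly for any
  admissible grid knee, and with small noise (standard deviation 0.01 on
  the mortality proportions, about the reporting precision of such
  curves) it stays within one grid step — both are asserted in the test
  suite over randomised knees.
* On a *real* (or realistically simulated) cohort the visible knee of the
  `at_or_above` curve sits **below** the generative knee: mortality among
  all women above $c$ mixes risk from both sides of the knee, and on a
  right-skewed index this drags the bend downward (the README example
  detects 0.16 where the latent knee is 0.25). The fit can be weighted by
  group size (`weighted = TRUE`), which is appropriate for cohort scans
  where high-cutoff groups are tiny. The threshold used for analyses is
  therefore a *configured* parameter informed by the scan, not blindly
  the scan output.

## Falls definitions and effect estimates

Falls are self-reported counts for the 12 months before each visit.
Categories are deterministic: 0 → no falls, 1 → one fall, ≥ 2 → recurrent.
Recurrent falling is the primary outcome on the view that repeated falls
reflect intrinsic multi-system decline, while a single fall is often
accidental. Records with missing falls data are represented explicitly
(`NA`) and excluded *at analysis time*, never at load time; every table
records its analysis n and exclusion count, because the shifting
denominators across waves are an easy source of silent errors.

Fall–frailty groups combine faller status (≥ 1 fall in the 12 months
before the classifying visit — no carry-forward from earlier waves) with
frailty status at that visit, giving the four groups
faller/frail … non-faller/non-frail.

Effect estimates come in three forms, all returned as `effect_estimate`
objects with 95% CIs:

* **2×2 tables** — cross-product odds ratio with the Woolf interval
  (log-OR ± 1.96·√(1/a+1/b+1/c+1/d)). Any zero cell triggers the
  Haldane–Anscombe correction (0.5 added to every cell) and a flag; a
  zero margin is an error.
* **Logistic regression** — `stats::glm` maximum likelihood (IRLS,
  log-likelihood tolerance 1e-8), Wald CIs from exponentiated
  coefficients. Complete-case analysis with exclusion counts recorded
  (the adjustment covariates are serum 25(OH)D in nmol/L, BMI in kg/m²,
  smoking as a three-level factor with never-smokers as reference, and
  any prior fracture between ages 50 and 75). Fewer than 10 complete
  cases per parameter warns; separation (non-convergence or a diverging
  coefficient) errors, naming the offending term. For a single binary
  exposure the unadjusted logistic OR coincides with the 2×2
  cross-product OR; the suite enforces agreement within 1e-6, which is
  why the Woolf interval is a faithful stand-in for the
  regression-derived CI on unadjusted contrasts.
* **Per-0.01 increments** — the index is multiplied by 100 before
  fitting, so the exponentiated coefficient is the odds ratio per 0.01 of
  index, the conventional reporting scale for continuous frailty.

No multiple-testing correction is applied; p < 0.05 is treated as
nominally significant, matching the descriptive character of the
analyses.

`run_full_analysis()` orchestrates everything — baseline characteristics
by frailty status, quintile × falls tables per visit pairing, fall–frailty
group proportions and ORs (within-stratum frail vs non-frail, and all four
groups against the robust non-faller/non-frail reference), frailty-status
and increment ORs, and per-visit falls incidence — and `write_report()`
serialises the lot as CSVs plus one JSON summary.

## The synthetic cohort generator

The generator exists so that every stage is testable and parameter
recovery can be asserted; person-level data from the motivating cohort are
not public. It is **latent-index-first**: the latent frailty trajectory is
sampled directly, and raw deficits are then constructed to be consistent
with it. Sampling deficits first and hoping the index distribution comes
out right would make calibration fragile; the analyses consume the index,
so the index distribution is what must be controlled.

Per woman:

1. **Baseline index** from a Beta(2.238, 10.387) distribution — calibrated
   so the median is 0.16 and the IQR 0.14 (the Beta family then implies a
   mean of about 0.177; matching the median/IQR pair was prioritised over
   the mean). Follow-up values add a calibrated drift (+0.065 at five
   years, +0.130 at ten) plus Gaussian noise (SD 0.03/0.04), clamped to
   [0, 1]; among surviving attendees this reproduces median indices of
   about 0.21 and 0.27 at the follow-ups.
2. **Deficits.** Four binary deficits are Bernoulli with probability
   0.7 × index (diseases are rarer than graded impairments). The nine
   continuous item scores are then *water-filled*: scaled random weights
   are raised or lowered by a common factor (bisection, fully vectorised)
   until the thirteen scores sum to exactly 13 × index, each clamped to
   [0, 1]. The rebuilt index therefore equals the latent index exactly
   except where the binary draw makes the total infeasible (well under
   10% of records, small clamping error) and where the 1% per-item
   missingness drops an item from the mean. The suite asserts median
   reconstruction error < 0.001 and 95th percentile < 0.05.
3. **Falls.** Two logistic models on the latent index — log-odds
   log(1.04) per 0.01 for ≥ 1 fall and log(1.05) per 0.01 for recurrent
   falls — with per-visit intercepts solved at generation time so the
   attendee incidence hits the calibrated targets (28.4%/31.0%/44.7% for
   any fall; 14.7%/17.6%/26.4% recurrent). A single uniform draw is
   compared against both probabilities (nested), so a recurrent faller is
   always a faller. Counts above two add a negative-binomial tail
   (dispersion 1.2, mean 0.5 + 2.5 × index), chosen as a modelling
   convenience: the observed data constrain only the 0/1/2/3+ categories,
   not the full count distribution.
4. **Mortality and attrition.** Ten-year death risk is flat (0.30) below
   index 0.25 and rises by 1.5 per unit index above it; 38% of deaths
   fall in the first five-year interval. Attendance among survivors
   declines with current frailty (log-odds −0.04 per 0.01 of index), with
   intercepts solved so the expected attendee counts are 715 and 382 out
   of 1044; dropout is monotone (no returns). Infeasible targets (more
   attendees than surviving eligibles) raise a configuration error.
5. **Covariates** (BMI, 25(OH)D, smoking, prior fracture) are drawn at
   baseline with mild frailty dependence matching the frail/non-frail
   contrasts of the motivating cohort, and carried forward.

All calibration constants live in one file
(`inst/extdata/generator_calibration.yaml`), labelled as calibration
values. Falls-data missingness is 12.45% at baseline and 0.56% at five
years, reproducing valid-falls denominators of about 914 and 711.

**What the generator does not emulate:** the real covariance structure
among deficits (items are conditionally coupled through the latent index
only), reasons for non-attendance beyond frailty, cognitive decline,
recall bias in self-reported falls, and any fracture outcomes. Passing
recovery tests therefore shows the *estimators* are consistent and well
calibrated under the assumed structure — not that the assumed structure
is the truth of any real cohort.

**Recovery experiments.** `recovery_experiment()` repeatedly generates,
re-builds the index *through the package pipeline* (so measurement error
from reconstruction and item missingness is included), fits the baseline
models, and summarises bias, Wald coverage and rejection rate for the
per-0.01 OR and the frail-vs-non-frail OR. The truth for the group OR is
not a configured constant; it is the population OR implied by the latent
model, computed per replicate from the generator truth. The test suite
runs 100 replicates at n = 1044 for the effect model and 200 under the
null, sizes chosen to keep Monte-Carlo error on coverage and type-I error
around one percentage point while the whole suite stays fast.

## Known limitations

* The knee of an empirical `at_or_above` mortality scan is attenuated
  relative to a generative threshold (see above); treat the scan as
  decision support for choosing the cutoff, not as an estimator of a
  sharp biological threshold.
* Woolf/Wald intervals are first-order; with very sparse cells the
  Haldane–Anscombe correction is a crude fix and profile-likelihood or
  exact intervals would be preferable.
* Adjusted models use complete cases; covariate missingness is assumed
  ignorable and no imputation is offered.
* The deficit list is fully configuration-driven: apart from the
  published steps-to-walk-30-m range, item cut-points and ranges are not
  fixed by the package and must be supplied (or determined from data via
  `determine_ranges()`).
* No survival-time modelling: mortality enters only as a 10-year binary
  flag, by design.
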