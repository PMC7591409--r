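# frailtyfalls

Deficit-accumulation frailty index and recurrent-falls analysis for
longitudinal cohorts of older women.

## The problem

In community-dwelling older women, frailty and falls feed each other: frail
women fall more, and falls accelerate frailty. Untangling the two requires a
*continuous* frailty measure (categorical definitions lose the gradient), a
principled frailty threshold, and analyses that separate women who have
already entered the falls–frailty cycle from those who have not.
`frailtyfalls` packages that workflow for single-age cohorts followed in
waves (by default ages 75, 80, 85, mirroring the OPRA cohort of 1044
Swedish women, whose person-level data are not public):

* **Frailty index** — a 13-item deficit-accumulation index in the Searle
  tradition. Each deficit is scored 0 (healthy) to 1: binary items are
  dichotomised at a cut-point, continuous items are min–max rescaled,
  `(V_x − V_min) / (V_max − V_min)`, after fixing `V_min`/`V_max` from the
  observed range with extreme outliers excluded. The index FI is the mean
  item score over non-missing items (≥ 80% completeness required), so
  FI ∈ [0, 1] with higher values meaning more accumulated deficits.
* **Empirical cutoff** — women with FI ≥ 0.25 are classified frail. The
  cutoff is motivated by 10-year mortality: scanning candidate cutoffs in
  0.02 increments and fitting a continuous two-segment piecewise-linear
  model locates the beginning of the steeper slope of the mortality curve.
* **Falls analyses** — falls are self-reported counts for the 12 months
  before each visit; *recurrent falls* (≥ 2) is the primary outcome.
  The package produces frailty-quintile × falls-count gradients with
  chi-square tests, combined fall–frailty groups
  (faller/non-faller × frail/non-frail), and odds ratios — from 2×2 tables
  (Woolf CIs, Haldane–Anscombe correction when needed), from logistic
  regression (unadjusted and adjusted for 25(OH)D, BMI, smoking and prior
  fracture), and per 0.01 increment of the index.
* **Synthetic cohorts** — a calibrated generator (latent frailty
  trajectory first, deficits reconstructed from it) with
  frailty-dependent falls, mortality and attrition, so the whole pipeline
  is testable and parameter recovery can be verified without study data.

## Worked example

```r
library(frailtyfalls)

sim <- generate_cohort(generator_config(n_baseline = 1044, seed = 42))
cohort <- sim$cohort
cohort
#> <falls_cohort> 1044 participants, 3132 visit records, 13 deficits
#>   age 75: 1044 records, 1044 attended, 920 with falls data
#>   age 80: 1044 records, 717 attended, 716 with falls data
#>   age 85: 1044 records, 378 attended, 378 with falls data

fi <- build_frailty_index(cohort, index_config(cutoff = 0.25))
baseline <- subset(fi, visit_age == 75 & complete)
round(c(median = median(baseline$index), IQR = IQR(baseline$index),
        frail_pct = 100 * mean(baseline$frail)), 3)
#>    median       IQR frail_pct
#>     0.159     0.137    21.764

report <- run_full_analysis(cohort)
report
#> <falls_report>
#> Falls incidence per visit:
#>  visit_age n_falls_valid pct_any_fall pct_recurrent
#>         75           920         26.5            15
#>         80           716         35.1            19
#>         85           378         43.7            27
#>
#> Frailty-status odds ratios for recurrent falls:
#>   frail at 75 -> recurrent falls at 80: OR 2.56 (1.65-3.97), n = 715
#>   frail at 75 -> recurrent falls at 85: OR 2.20 (1.16-4.18), n = 378
#>   frail at 80 -> recurrent falls at 85: OR 1.50 (0.93-2.41), n = 378
```

The cohort thins from 1044 to 717 to 378 attendees through frailty-dependent
death and non-attendance; the median index and falls incidence rise with
age; and being frail at 75 roughly doubles to triples the odds of recurrent
falls five and ten years later — the structure the analyses are built to
expose. `write_report(report, "out/")` writes every table as CSV plus a
JSON summary with all estimates, CIs and analysis n.

The empirical-cutoff machinery works on any baseline index paired with
10-year vital status:

```r
died10 <- with(cohort$visits,
               !alive[visit_age == 85][match(baseline$participant_id,
                                             participant_id[visit_age == 85])])
scan <- scan_mortality(baseline$index, died10)   # 0.02-step candidate grid
detect_slope_change(scan, weighted = TRUE)
#> <slope_change> changepoint at 0.160 (slopes 0.026 -> 1.059)
```

On this synthetic cohort the steeper mortality slope is detected at 0.16
rather than at the generator's latent knee of 0.25: mortality *among all
women at or above* a candidate mixes risk from both sides of the knee,
which drags the visible bend downward on a right-skewed index. The methods
vignette discusses this attenuation; on exact two-segment curves the
changepoint is recovered exactly (see the test suite).

A command-line interface wraps the same functions
(`inst/cli/frailtyfalls.R`): subcommands `simulate`, `build-index`,
`cutoff-scan`, `analyze` and `recover`, each writing a manifest with seed,
versions and input checksums.

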