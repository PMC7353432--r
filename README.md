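# vitdfort

Modelling vitamin D status from dietary intake, and simulating the impact
of fortified breakfast cereals, in survey populations.

Vitamin D status — serum 25-hydroxy-vitamin D, 25(OH)D, in nmol/L — is low
across the UK population, and ready-to-eat breakfast cereals (RTEC) are a
candidate fortification vehicle because nearly everyone eats them.
vitdfort is an R package for nutrition epidemiologists who want to ask,
with survey data of the National Diet and Nutrition Survey (NDNS) kind:
how does status respond to intake, how strong is the seasonal (UV) cycle,
and what would fortifying cereals at a given level do to population
status? Because the underlying survey microdata are access-restricted, the
package also ships a calibrated synthetic-cohort generator that reproduces
the published cohort summaries, so the entire pipeline is runnable and
testable out of the box.

## The models

**Dose-response.** Daily intake *x* (µg/day, diet + supplements) relates
to serum status *y* (nmol/L) through the saturating asymptotic
(pseudo-Hill) form

> *y* = *a* + *b* (1 − e^(−*c x*)),  plateau = *a* + *b*,

fit by nonlinear least squares, with closed-form inversion
*x* = −ln(1 − (*y* − *a*)/*b*)/*c* for questions like "what intake reaches
50 nmol/L?".

**Season.** Serum status by blood-draw month *m* (1 = January) follows a
concave quadratic *y* = α*m*² + β*m* + γ whose peak month is
−β/(2α), with a first-harmonic cosine/sine model as comparator.

**Fortification counterfactual.** Each RTEC consumer's intake is shifted
by `grams × level / 100` µg/day, serum is recomputed from the cohort's
dose-response curve with the month-specific seasonal deviation held
constant, and the package reports per-cohort gains and threshold
prevalences (below 25/50, above 75/100 nmol/L).

Supporting statistics match survey practice: Taylor-linearized means and
SEs over strata and primary sampling units, the design-df-adjusted Wald
test, and iterative two-sided Grubbs outlier screening.

## Worked example

```r
library(vitdfort)

# The children's (4-10 y) fitted intake-status curve, from its coefficients
children <- dose_response(21.38, 30.77, 2.42)
children
#> Saturating dose-response: y = a + b(1 - exp(-c x))
#>   a = 21.380 nmol/L, b = 30.770 nmol/L, c = 2.4200 per ug/day
#>   plateau = 52.15 nmol/L, n = ?

round_half_up(invert_for_intake(children, 50), 1)   # intake reaching 50 nmol/L
#> [1] 1.1

# Full pipeline on the calibrated synthetic survey (n = 3770)
cfg <- default_generator_config(seed = 1)
report <- run_pipeline(cfg, fortification_scenario(level = 4.2))

report$summary$serum
#>   cohort  mean    se    sd     n pct_below_25 pct_below_50 pct_above_75 ...
#> 1 11-18   45.1 1.25   22.3   319        19.1          59.9        10.0
#> 2 19-64   44.6 0.854  23.9   782        21.6          58.2        10.1
#> 3 4-10    53.0 1.61   21.5   177         9.04         45.2        16.4
#> 4 65plus  41.7 1.58   22.0   193        25.9          65.8         6.74

dplyr::select(report$fortification$summary, cohort, gender, difference_mean, n)
#>   cohort gender difference_mean     n
#> 1 11-18  female            3.15   290
#> 2 11-18  male              2.71   299
#> 3 19-64  female            2.94   625
#> 4 19-64  male              3.04   416
#> 5 4-10   female            1.98   335
#> 6 4-10   male              1.26   369
#> 7 65plus female            6.54   185
#> 8 65plus male              7.85   131
```

The serum table mirrors the published cohort summaries: status is highest
in children (~53 nmol/L) and lowest in the elderly (~42 nmol/L), with
roughly a fifth of the older cohorts below the 25 nmol/L deficiency
threshold. The fortification block shows the mean per-person serum gain
from cereals fortified at 4.2 µg/100 g among RTEC consumers: smallest in
children (~1.3 nmol/L, whose steep curve is already near its plateau) and
largest in the elderly (~6.5–7.9 nmol/L, who eat the most cereal and sit
on the shallowest part of their curve). `autoplot()` methods draw each
fitted object; `tidy()`/`glance()` return coefficient and summary tibbles.

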