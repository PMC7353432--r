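---
title: "Modelling vitamin D status and cereal fortification with vitdfort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vitamin D status and cereal fortification with vitdfort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdfort)
library(dplyr)
```

vitdfort models how serum 25-hydroxy-vitamin D (25(OH)D, nmol/L) — the
standard biomarker of vitamin D status — responds to daily vitamin D intake
(µg/day) and to the annual UV cycle in a national diet survey population,
and simulates what fortifying ready-to-eat breakfast cereals (RTEC) would
do to that status. This vignette explains the models, their assumptions,
the tunable parameters, the synthetic-cohort generator used throughout the
test suite, and the numerical choices and limitations a careful user
should know about.

## The dose-response model

Dietary vitamin D is one of two supply routes for 25(OH)D (the other being
cutaneous synthesis under UVB). Across a population the relationship
between total daily intake $x$ (diet plus supplements, µg/day) and serum
status $y$ (nmol/L) saturates: above some intake, additional vitamin D
moves the biomarker very little. vitdfort uses the asymptotic
(pseudo-Hill) form

$$ y = a + b\,\bigl(1 - e^{-c x}\bigr), $$

with baseline $a$ (status at zero dietary intake, carried by UV exposure
and body stores, nmol/L), span $b > 0$ (nmol/L) and rate $c > 0$ (per
µg/day). The **plateau** $a + b$ is the asymptotic status at unbounded
intake; the curve is strictly increasing and concave, so the marginal gain
from one extra µg/day, $b\,c\,e^{-c x}$, falls with intake. The model has
a closed-form inverse,

$$ x(y) = -\tfrac{1}{c}\,\ln\!\bigl(1 - (y - a)/b\bigr), \qquad a < y < a+b, $$

used to answer "what intake reaches 50 nmol/L?". Targets at or above the
plateau are rejected as unreachable rather than extrapolated.

```{r dose-response}
children <- dose_response(21.38, 30.77, 2.42)   # a, b, c
plateau(children)
invert_for_intake(children, 50)
marginal_gain(children, intake = 2.6, delta = 1)
```

`fit_dose_response()` estimates $(a, b, c)$ by nonlinear least squares
(Levenberg–Marquardt, via minpack.lm) treating observations as
independent. Choices a user may care about:

* **Start values** are data-driven: $a_0 = \min y$, $b_0 = \max y - \min
  y$, $c_0 = 1/\bar x$. They put the initial curve through the data's
  vertical range with a rate scaled to the observed intakes.
* **Bounds**: $b, c \ge 10^{-6}$. Unbounded, a flat response lets $(a, b)$
  trade off freely; the bound keeps the parameterization identifiable and a
  fit pinned at it raises a `boundary` flag and a warning (a flat response
  degenerates to $a \approx \bar y$).
* **Plateau CI** is a delta-method 95% interval on $a + b$ from the
  coefficient covariance at the optimum (t quantile at $n - 3$ df). With
  small rate constants the plateau is an extrapolation and the interval is
  honest about that — it can be very wide.
* Survey-design-aware standard errors are deliberately *not* computed
  here; they belong to the survey statistics below.

Numerically, prediction and inversion use `expm1()`/`log1p()`. Even so,
once $c\,x \gtrsim 25$ the predicted serum is indistinguishable from the
plateau in double precision, so inversion round-trips to $10^{-9}$ only
where the curve is numerically below its asymptote (roughly $c\,x \le
14$); beyond that the inverse is ill-posed by the mathematics, not the
implementation.

## The seasonal model

Within a year, UV exposure drives 25(OH)D up in summer and down in winter.
With the blood-draw month coded $m \in \{1,\dots,12\}$ (1 = January), the
primary model is the concave quadratic $y = \alpha m^2 + \beta m + \gamma$
($\alpha < 0$), whose maximum is found analytically from the first
derivative at $m^\ast = -\beta/(2\alpha)$. A first-harmonic cosine/sine
model with a 12-month period is retained as the wrap-aware comparator
(`fit_trig_season()`, `compare_seasonal_models()`); both spend three
parameters, so the comparison reports $R^2$ for each and the residual
sum-of-squares ratio descriptively rather than a nested test.

The quadratic treats months as a plain integer covariate with no
December-to-January wrap-around. That discontinuity is a deliberate
modelling choice: it reproduces the analysis convention this package
implements, and in practice the UK annual cycle is far from the year
boundary (peaks fall in July–September), so the wrap matters little.

```{r seasonal}
adult_males <- seasonal_fit(-0.65, 10.58, 10.38)
peak_month(adult_males)           # early August
seasonal_deviation(adult_males, c(2, 8))
```

`seasonal_deviation()` centres the fitted curve by subtracting its mean
over the twelve months, so deviations sum to zero across a year. This
centred deviation is the seasonal component shared by the cohort simulator
and the fortification engine.

Reported peak months are rounded half-up to one decimal (8.05 reports as
8.1); all internal computation keeps full precision.

## The fortification counterfactual

The fortification question is: if RTEC carried $L$ µg vitamin D per 100 g,
how would each survey participant's status change, all else held equal?
The baseline level $L = 4.2$ comes from a labelling rationale: a breakfast
should supply 25% of the 5 µg/day labelling RDA, i.e. 1.25 µg, from a 30 g
dry-weight portion — `derive_fortification_level(5, 0.25, 30)`. A newer
per-serving convention (2.5 µg per 30 g serving) corresponds to
$L = 8.33$.

For a participant with total intake $x$, RTEC consumption $R$ g/day and
blood-draw month $m$, the two arms are

$$ y_{\text{without}} = f(x) + s(m), \qquad
   y_{\text{with}} = f(x + R L / 100) + s(m), $$

where $f$ is the cohort's dose-response curve and $s$ the centred seasonal
deviation — the *same* $s(m)$ in both arms, so UV exposure is held
constant and the month cancels exactly from every with-minus-without
difference (a property the tests assert to $10^{-12}$). Both arms are
model-based: measured serum is not used, and non-consumers ($R = 0$) are
excluded by default since fortification cannot reach them (switchable via
`consumers_only = FALSE`, where they appear with a difference of exactly
zero). Differences are nonnegative by monotonicity, bounded by the
plateau headroom, and increase with $R$ at diminishing rates.

Threshold prevalences (below 25/50, above 75/100 nmol/L by default) use
strict inequalities; a value exactly at a threshold counts in neither
tail. The 25 nmol/L threshold is the UK deficiency cut-off, 50 nmol/L the
sufficiency target, and 75/100 nmol/L are reported because very high
status carries its own risks.

## The synthetic cohort generator

The restricted survey microdata behind this kind of analysis cannot be
redistributed, so vitdfort ships a generator whose default configuration
(`default_generator_config()`) reproduces the *published* statistical
surface of the 2008–2012 UK National Diet and Nutrition Survey waves: four
age cohorts (4–10, 11–18, 19–64, 65+, total $n = 3770$) crossed with
gender. Per cell it emulates:

* **Dietary intake**: lognormal, moment-matched to the published
  non-supplement-taker mean and s.d. Lognormality is forced by the data:
  intakes are positive and several cells print s.d. larger than the mean,
  which no untruncated normal can produce.
* **Supplement taking**: Bernoulli at the published prevalence (5–32%
  depending on cell); takers receive a lognormal supplement dose whose
  mean is the published taker-vs-non-taker gap, added to dietary intake.
  The published "all persons" rows then emerge as the mixture.
* **RTEC consumption**: a consumer fraction per cell (60–89%, from the
  published consumer counts), lognormal grams for consumers. Means follow
  the published pattern — about 30 g/day in children rising to 40 g/day in
  adults and 65 g/day in the elderly, males above females — with a
  coefficient of variation of 0.6, a typical dispersion for diary-recorded
  staple foods. The teenage means (not printed anywhere) are set between
  children and adults, wide enough apart by gender to reproduce the
  published significant male-female difference.
* **Blood sampling**: independent Bernoulli per participant at the
  published response fractions (0.20 children, 0.35 teenagers, 0.47
  adults/elderly); records without a draw carry a missing serum.
* **Months**: uniform over 1..12 — the survey's true draw-date
  distribution is unpublished, and uniformity keeps the seasonal centring
  exact.
* **Design ids**: 36 PSUs spread round-robin over 9 strata (one per
  Government Office Region, the survey's stratification variable),
  participants assigned round-robin over PSUs.
* **Serum**: the additive composition `dose_response(intake) +
  centred_seasonal_deviation(month) + N(0, sigma)`. The source analysis
  fits the intake model and the seasonal model separately on the same
  outcome; an additive model with a centred seasonal term is the minimal
  joint model consistent with both marginal fits, and it makes the annual
  mean of simulated serum at fixed intake equal the dose-response value
  exactly.

The residual noise $\sigma$ per cohort is *derived*, not hand-picked: the
target marginal serum s.d. (21.8–24.6 nmol/L, published per cohort) minus
the variance contributed by the intake distribution pushed through the
dose-response curve (computed by deterministic quantile-grid quadrature
over the lognormal mixture) and by the seasonal cycle under uniform
months. No random numbers are involved in the calibration, so identical
configs are bit-identical. Simulated serum is floored at 1 nmol/L — with
cohort means near 45 and noise s.d. near 20 a Gaussian tail would
otherwise produce ~1–2% nonpositive values, which serum cannot take.

A seed is mandatory; identical configurations generate bit-identical
record tables. `summarize_cohort()` reproduces the layout of the published
intake and status tables, and at the published sample sizes the simulated
cell means land within ordinary sampling error (three standard errors) of
their targets.

### What the generator does *not* emulate

Household and postcode sampling mechanics, diary-level food items,
ethnicity (absent from the source data), intake-month correlation (intake
and serum are linked only through the dose-response curve), within-person
repeated measures, and any true non-uniformity of blood-draw dates. A test
that passes on this synthetic population certifies the *pipeline* —
estimators, counterfactual logic, reporting — under the published
population structure; it cannot certify conclusions about the real cohort
beyond that structure.

## Survey statistics

The published analysis runs in "survey mode": PSU = area, stratum =
region, clusters with replacement, no finite-population correction, and —
deliberately — no weighting. `survey_mean()` implements the matching
Taylor-linearization estimator: per-record scores $w_i (y_i -
\hat\mu)/\sum w$ are totalled per PSU and their between-PSU variance
accumulated within strata with the factor $n_h/(n_h - 1)$. With one
stratum, singleton PSUs and unit weights this collapses exactly to the
classical $s/\sqrt n$ (asserted to $10^{-10}$). A stratum containing a
single PSU contributes no estimable variance; the SE is then reported as
`NA` with the stratum flagged, reproducing the "n.a." convention of the
published tables rather than silently centring on the grand mean.

`adjusted_wald()` tests equality of group means with the design-df
adjustment $F = \frac{d-k+1}{d\,k} W \sim F(k,\, d-k+1)$, $d$ = PSUs minus
strata, $k$ = contrasts; for one contrast it reduces to the squared t
(asserted to $10^{-8}$).

`grubbs_test()` is the two-sided single-outlier test, $G = \max_i |x_i -
\bar x|/s$ against the t-based critical value
$\frac{n-1}{\sqrt n}\sqrt{t^2_{\alpha/(2n),\,n-2}/(n - 2 + t^2)}$;
`remove_outliers()` iterates it one point per pass. Two-sided screening
was chosen because both implausibly high and implausibly low serum values
occur in practice. A zero-variance sample is a no-outlier verdict, not an
error. On clean normal samples the iterative screen triggers at close to
its nominal 5% rate (checked over 1,000 seeded replicates).

The published analysis also mentions a stepwise confounder-selection
regression; its entry criteria and candidate order are unpublished, so it
is out of scope here rather than guessed at.

## Problem sizes and verification

The test suite regenerates every fixture in code. Recovery checks fit
synthetic cohorts of 5,000 serum observations across 20 seeds per cohort
and require the across-seed mean plateau within 5% of truth. Seasonal
peak recovery at the published per-cell sample sizes is held to 0.5 months
where the design identifies the peak that precisely — judged *a priori* by
the delta-method standard error of $-\beta/(2\alpha)$ at the cell's $n$,
curvature and calibrated noise — and to median recovery within one design
SE in the under-powered cells (at $n = 74$ with shallow curvature the peak
estimator is a heavy-tailed ratio with a spread of over a month; no
implementation could recover it to half a month, and pretending otherwise
would overstate what the published peak for such cells can mean).
Generator calibration is checked on the mean of five full survey
replicates against a $3\,\mathrm{SE}/\sqrt 5$ band, a stricter test than
any single draw. The full suite runs in well under a minute.

## Known limitations

* The dose-response fit ignores the survey design; design-aware
  uncertainty for derived quantities (plateau, inversion) is not
  propagated.
* The elderly cohort's small rate constant makes its plateau an
  extrapolation far beyond observed intakes; its interval is wide and any
  downstream use should carry that uncertainty.
* The counterfactual assumes fortification changes no one's consumption
  behaviour and treats the dose-response as causal for an intake shift.
* Threshold prevalences from the model-based counterfactual understate
  real between-person dispersion, because the modelled serum carries only
  intake and season, not residual biology.
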