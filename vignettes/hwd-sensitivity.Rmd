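---
title: "Comparing heat wave definitions against heat-related illness counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing heat wave definitions against heat-related illness counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hwdsens)
```

## The problem

Public-health heat warnings rest on a definition of "heat wave", but no
single definition is standard. A definition is a rule built from a heat
metric, a duration requirement, and a threshold. Different rules flag very
different sets of days, and the rule that best predicts health burden
varies by region. `hwdsens` treats this as a model-selection problem: fit
the same daily count model once per candidate definition, with only the
heat-wave flag changing, and rank the fits by AIC. The package encodes a
28-definition grammar (`standard_definitions()`): mean, maximum and
minimum temperature each crossed with 2+/3+ consecutive days and the
99/98/95/90th climatological percentiles; one absolute single-day rule
(maximum temperature > 35 °C); and three single-day maximum apparent
temperature rules at the 95/90/85th percentiles.

## From station data to flags

Station observations are averaged, unweighted, to one value per region and
day. An unweighted mean is the simplest defensible aggregation; it is
deliberately isolated in `aggregate_to_region()` so an area- or
inverse-distance-weighted variant can be swapped in without touching
anything downstream.

Relative humidity comes from the August–Roche–Magnus ratio with constants
17.625 / 243.04 °C; a dew point above the air temperature (which occurs in
real station records) clamps to 100% with a warning rather than erroring.
Maximum apparent temperature uses the NWS algorithm: the Rothfusz
regression in °F, the Steadman simple formula when its average with the
temperature falls below 80 °F, and the standard low-humidity (RH < 13%,
80–112 °F) and high-humidity (RH > 85%, 80–87 °F) adjustments. The result
is *not* rounded to whole degrees by default: percentile thresholds are
carried at 0.01 °C precision, and rounding would quantize them. Some
published implementations round; `heat_index(round_f = TRUE)` reproduces
that behaviour.

Percentile thresholds use linear interpolation between order statistics
(position h = (n−1)·p/100 + 1; `stats::quantile` type 7). The method is a
documented argument because other interpolation rules move thresholds by
a few hundredths of a degree, which can move a handful of flag days.

Flagging is strict: a day exceeds only when its metric is strictly greater
than the threshold, so a day exactly at an absolute 35 °C cutoff does not
count. For k+ definitions a day is flagged iff it belongs to a maximal run
of ≥ k consecutive exceedance days. Runs break at missing values (a
missing day is never flagged — the conservative choice, since it never
invents exposure) and at calendar gaps, so heat cannot "accumulate" across
the winter between one 30 September and the next 1 May, while the
31 May → 1 June boundary inside a season is seamless.

## The count model

For each region and definition:

log E(count) = log(population) + β₀ + β_HW·HW + β_RH·RH + β_NWS·NWS +
β_weekend + month + year,

with NB2 variance μ + μ²/θ. Relative humidity is included for plain
temperature metrics and excluded for apparent-temperature metrics, which
already combine temperature and humidity; including it twice would adjust
away part of the exposure. The NWS alert flag absorbs the behavioural
effect of an active warning. Month (reference May) and year (reference
first study year) factors and a Saturday/Sunday indicator absorb seasonal
and secular structure; all reference levels are conventions, not
substantive choices, and are isolated in `build_design()`.

`fit_nb()` is a self-contained NB2 maximum-likelihood fitter: IRLS for the
coefficients at fixed θ, alternated with a one-dimensional ML update of θ
(golden-section on log θ over [1e−4, 1e7]), until the joint log-likelihood
changes by less than 1e−10 (relative). Standard errors use the expected
information at the converged fit with θ fixed — the convention of the
standard NB-GLM toolchain, which the test suite uses as an independent
cross-check (coefficients, θ, log-likelihood, standard errors and AIC
agree to at least 4 significant figures on seeded datasets). AIC counts θ
as a parameter: AIC = 2(p+1) − 2 log L. A definition whose flag series is
constant in a region (e.g. an absolute cutoff never exceeded) has an
inestimable β_HW; the fit is recorded as NA with a warning and excluded
from ranking rather than silently dropped. AIC ties break lexicographically
by definition id so ranking is deterministic.

Counts below 5 arrive suppressed from surveillance systems;
`impute_censored()` substitutes the constant 3 (the reported median of
suppressed days). The cutoff and constant are arguments. Imputation by a
constant understates variance and can bias β_HW when censoring correlates
with exposure; the synthetic generator exposes exactly this (the raw,
uncensored counts are retained alongside), so the bias is measurable
rather than assumed away.

Agreement with NWS alert days uses the McNemar test on the paired 2×2
table of (definition flag, alert flag) days. The continuity-corrected form
(|b−c|−1)²/(b+c) is the default — the published statistics this package's
worked examples reproduce are only consistent with the corrected form —
with the numerator clamped at zero so the statistic stays defined when the
discordant cells nearly agree.

## What the synthetic generator emulates

`synthetic_config()` defaults define one fixed scenario: two regions, five
summer seasons (1 May–30 September; 765 study days per region), a 120-year
baseline climatology, and:

* regional daily maximum temperature = seasonal sinusoid (peak 33 °C
  mid-July, seasonal half-range 14 °C) + AR(1) anomaly (φ = 0.7,
  innovation sd 2.2 °C, restarted each season); the study era sits
  +2.5 °C above the baseline era, standing in for the warming that makes
  climatological percentile exceedances common in recent years;
* stations observe the regional value plus 0.8 °C noise; tmin is tmax
  minus a ~9 °C diurnal range; dew point is tmax minus a gamma deficit
  (mean 7 °C);
* alerts cover the top ~2.5% of apparent-temperature days, grouped into
  intervals — the sparsity regime of real heat products;
* counts are NB2 (θ = 5) from the model's own linear predictor with a
  true heat-wave rate ratio of 2.75, and days below 5 are suppressed.

These values were fixed once, by the criteria that 2+-day/90th-percentile
definitions should flag ~25–35% of study days, the censoring fraction
should sit near 29%, and daily counts near 5–10 — the regime the method is
meant for. Measured at the default scenario the realized values are ~25–31%
flagged, 30% censored, mean ~9.6 visits/day. Each stage draws from its own
seed stream derived from the master seed by a fixed label, so adding a
stage never perturbs another stage's draws.

What the generator does **not** emulate: spatial station heterogeneity
(two exchangeable stations per region), humidity–temperature dependence
beyond a subtractive deficit, outcome autocorrelation beyond what the
covariates induce (daily counts are conditionally independent), reporting
artifacts (weekday surges, holidays), and alert issuance based on
forecasts rather than realized weather. Passing tests therefore show the
machinery is correct and the design identifiable under the stated model —
not that any particular definition is optimal for a real region.

## Numerical choices and edge cases

* Percentile interpolation: order-statistic linear interpolation, `type`
  exposed; baselines are dropped of missing values and must be nonempty.
* Exceedance ties: strict `>` everywhere; ties are non-exceedances.
* `fit_nb` starts from a Poisson fit and a moment estimate of θ, clamped
  to [1e−3, 1e6]; rank-deficient designs error naming the offending
  column; non-convergence errors carry the recent log-likelihood trace.
* Saturation humidity is computed as a single exponential of the
  log-ratio so `dewpoint_to_rh(t, t)` is exactly 100.
* Weekday classification uses ISO weekday numbers (`format(date, "%u")`),
  immune to locale.
* McNemar with b + c = 0 errors (undefined) rather than returning 0.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
default study size (765 days × 28 definitions × 1–2 regions) with
shortened baselines of 30–60 climatology years — the percentile estimator
sees 4,590–9,180 baseline days per region, ample for stable 85–99th
percentiles — and use 25 replicates for the end-to-end recovery property
and 100 for coefficient coverage. A single full run takes a few seconds.

## Known limitations

Constant-imputation of censored counts is crude (a censored-likelihood fit
would be principled); the NWS flag enters only contemporaneously (no lag);
rate ratios are Wald intervals on the log scale; and AIC comparison across
definitions shares the outcome series, so ranked differences of a few AIC
units are not strong evidence — the end-to-end tests accept any definition
whose flags are near-equivalent (Jaccard ≥ 0.8) to the generating one for
exactly this reason.
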