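---
title: "Counterfactual precipitation from the cwv pickup relation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual precipitation from the cwv pickup relation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rainpickup)
```

## The model

Hourly precipitation over tropical land is, to first order, a function of
how much water the atmospheric column holds. Empirically the relation is a
*pickup*: precipitation is negligible until column water vapor (cwv)
reaches a critical value — around 60 mm over the flat southern Amazon —
and rises steeply above it. `rainpickup` treats this empirical relation as
the transfer function between a change in atmospheric moisture and a
change in rainfall.

The analysis has three ingredients.

**The conditional quartile curve.** For every 1-mm cwv bin we compute the
25th, 50th and 75th percentiles of all hourly precipitation values in that
bin, dry hours included — the near-zero conditional medians at low cwv are
the dry regime itself, not missing data. A bin participates only if it
holds more than five points, and cwv is retained below 73 mm, above which
reanalysis-style data become too sparse for stable quartiles.

**Quantile-ratio scaling.** Given monthly per-cell transpired fractions
$f_t \in [0,1]$, the counterfactual water vapor of each hour is
$\mathrm{cwv}_t = (1-f_t)\,\mathrm{cwv}$, and the counterfactual
precipitation is $p_{t,q} = f_q\, p$ with
$f_q = p_q(\mathrm{cwv}_t)/p_q(\mathrm{cwv})$. Each hour keeps its own
temporal position: rain falls when it actually fell, only weaker. The
three quartiles give a central estimate (q = 50) and an uncertainty
bracket; because lower-quartile curves are relatively steeper, the q = 25
reduction is the largest and the q = 75 reduction the smallest.

**Monte Carlo resampling.** As an independent estimator, each hour's
counterfactual precipitation is drawn with replacement from *all* observed
precipitation values in the 1-mm bin containing that hour's
$\mathrm{cwv}_t$. This preserves the full conditional distribution —
including the zero mass — but scrambles temporal structure, so only daily
totals and their distribution are summarised from it.

Key assumptions inherited from this design: wind fields and circulation do
not react to the moisture removal; the relation carries no temperature
dependence (defensible where temperature is nearly constant year-round);
and the observed cwv series is not itself depleted by precipitation
events. The `post_event_cwv_change()` diagnostic checks the latter on any
hourly series by comparing mean cwv in symmetric windows before and after
rainfall events; its defaults (events at $\ge 1$ mm/h, 3-h windows, 6-h
separation, bootstrap interval on the mean delta) are deliberately simple
and configurable, and the diagnostic is an approximation of such checks,
not a prescribed procedure.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `bin_width` | 1 | mm | cwv bin width for curves and pools |
| `min_count` | 6 | points | bin validity (strictly more than five) |
| `max_cwv` | 73 | mm | upper retention cutoff |
| wet-day cutoff | 0.01 | mm/day | day enters event statistics |
| `eps` | 1e-9 | mm/h | dry threshold in quantile ratios |
| `w_c` | 60 | mm | generator pickup threshold |
| `a`, `beta` | 0.06, 2 | — | generator law; median 1.5 mm/h at 65 mm |
| `f_t` mean | 0.13 | — | mean transpired fraction |

The quartile estimator is linear interpolation between order statistics
(the "type 7" convention) — the most widespread default, and reproducible.
Bin membership is `floor(cwv / bin_width)`, left-closed, right-open.

## Numerical conventions and edge cases

* **Lookups** are piecewise constant on bins. A cwv value in an invalid or
  absent bin falls back to the nearest *valid bin at lower cwv*; with none
  below, the result is 0 (below the observed pickup range nothing falls).
  Values above the highest valid bin take that bin's value. The same
  lower-side fallback governs empty Monte Carlo pools: it can only reduce,
  never inflate, the resampled rain.
* **Quantile ratios** at dry hours: when both quartiles are below `eps`
  the ratio is 1 (0/0 means "no rain before, no rain after"); a vanishing
  denominator with a non-vanishing numerator signals a non-monotone curve
  and yields 1 with a warning. With a monotone curve all factors lie in
  [0, 1] and all reductions in [0, 100]%.
* **Exponential fit**: nonlinear least squares on the original scale,
  initialized from a log-linear fit on `p + 1e-6` (a pure log transform is
  undefined on the dominant dry hours). Both fits report $R^2$ on the raw
  scale so they are comparable; only their ordering is a stable property.
* **Aggregation** sums hourly mm/h over complete periods only; partial
  periods are dropped with a warning. The area-wide series is the mean
  over cells. The wet-day filter is applied *independently* to observed
  and counterfactual daily series — the literal reading of removing dry
  days from each result — so the two medians may sit on different day
  sets; annual and monthly headline reductions are reported both as the
  median and the mean over cell-periods, since either convention is
  defensible for a single headline number.
* **Pools are area-wide** (one relation for the study area), matching the
  single area-wide quartile curve; per-cell curves are possible by calling
  the builders on per-cell subsets.
* **Seeds**: every stochastic function takes a seed; the Monte Carlo
  sampler derives an independent stream per cell, so per-cell results do
  not depend on cell iteration order. Identical seeds give bit-identical
  output.

## What the synthetic generator emulates — and what it does not

The generator exists so the full pipeline is testable without
non-redistributable reanalysis or moisture-tracking archives. Per cell it
draws cwv as mean + seasonal cosine + AR(1) noise, clipped to bounds
(defaults: mean 52 mm, amplitude 8 mm peaking mid-January, hourly
autocorrelation 0.95, innovation sd 2 mm, bounds 20–75 mm — a tropical
continental regime where a sizeable minority of wet-season hours exceed
the threshold). Precipitation follows
$p = a\,\max(0,\mathrm{cwv}-w_c)^\beta X$ with sub-threshold hours exactly
dry and $X$ lognormal with unit median, so the conditional median is the
law itself in closed form — which is what makes parameter-recovery tests
possible. The `sdlog` of $X$ tapers from 0.6 at the threshold to 0.3 ten
mm above it: a noise level chosen a priori so that binned medians estimate
the law at bin centers to within a few percent, and tapered so the
quartile curves are not parallel on the log scale (parallel curves would
make all three $f_q$ identical, collapsing the uncertainty bracket that
real pickup data show). Monthly $f_t$ is mean 0.13 with a westward
gradient (moisture accumulates downwind under easterly flow) and a
dry-season seasonal peak.

Not emulated: spatial correlation between cells, orography, wind,
post-event cwv depletion, and any temperature covariation. Passing tests
therefore demonstrate that the *estimators* recover known conditional
structure and that the pipeline's accounting is exact — not that real
Amazon data would yield any particular number.

Recovery checks compare binned estimates to the law *at bin centers*
(and quantile ratios to the ratio of center values): within a 1-mm bin the
law varies by up to a factor of four near the threshold, so comparing at
exact hourly cwv values would measure the deliberate 1-mm discretisation,
not estimation error.

## Problem sizes

The package's own test and reproduction runs use a 16-cell grid with two
simulated years (about 2.8 × 10⁵ cell-hours) for pipeline-level checks,
and eight simulated years (about 1.1 × 10⁶ cell-hours, cwv concentrated
between 55 and 72 mm) for parameter-recovery and cross-method runs — large
enough that every supercritical bin used in a comparison holds at least a
thousand points, and small enough that a full run completes in seconds.

## Known limitations

The quantile-ratio method inherits every limitation of a static transfer
function: no circulation response, no cascading re-evaporation accounting,
no temperature stratification. The Monte Carlo estimator preserves
distributions but not temporal structure, so sub-daily statistics from it
are meaningless by construction. Curves built from short series can be
non-monotone in sparse high-cwv bins; the ratio convention caps the
resulting factors at the cost of a warning rather than extrapolating. And
the generator's defaults are a plausible fixture, not a claim about any
real region: analyses of real data should feed their own fields through
the same tibble interfaces.
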