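# rainpickup

Counterfactual precipitation analysis from the nonlinear relation between
hourly precipitation and atmospheric column water vapor.

## The problem

Moisture-tracking studies estimate how much of a region's precipitation
originates from upwind evapotranspiration — for example, the share of
rainfall over the southern Amazon that was transpired by trees elsewhere in
the basin. Turning that share into a *precipitation change* usually assumes
linearity: remove 13% of the atmospheric moisture, lose 13% of the rain.
But over tropical land, hourly precipitation is a strongly nonlinear
function of column water vapor (cwv): it is negligible below a critical
value around 60 mm and rises sharply above it (the "pickup" relation
associated with the onset of deep convection). Under that relation, a
modest drop in cwv can push many hours below the convective threshold and
cause a disproportionately large loss of rainfall.

`rainpickup` quantifies this effect. Given hourly gridded cwv and
precipitation plus monthly per-cell transpired fractions `f_t`, it:

1. builds the empirical conditional quartile curve
   `p_q(cwv)` (`q = 25, 50, 75%`) by binning hourly precipitation every mm
   of cwv (bins valid when they hold more than five points, cwv retained
   below 73 mm), alongside linear and exponential fits of `p` on cwv;
2. constructs the counterfactual water vapor
   `cwv_t = (1 − f_t) · cwv` and scales each hour's precipitation by the
   quantile ratio

   `p_t,q = f_q · p`,  with  `f_q = p_q(cwv_t) / p_q(cwv)`;

3. alternatively, resamples each hour's precipitation with replacement from
   all observed values at similar (same 1-mm bin) `cwv_t` — a Monte Carlo
   estimator that preserves the conditional distribution but not the
   temporal structure;
4. aggregates to daily / monthly / annual totals, filters wet days
   (≥ 0.01 mm/day), and summarises percent reductions, seasonal cycles,
   and longitudinal/latitudinal profiles.

Because the reanalysis and moisture-tracking inputs such analyses use are
not redistributable, the package ships a first-class synthetic generator:
seasonal AR(1) cwv, a threshold pickup law
`p = a · max(0, cwv − w_c)^β · X` with unit-median magnitude noise, and
monthly `f_t` fields with a configurable mean (default 0.13), westward
gradient and seasonal cycle. Every analysis function is format-agnostic:
tibbles in, tibbles out.

## Worked example

```r
library(rainpickup)

run <- run_pipeline(default_config(seed = 1))
run
#> <run_report>
#>   16 cells x 17544 hours, seed 1
#>   mean transpired fraction: 12.98%; cwv reduction: 12.82%
#>   R^2 linear 0.236 vs exponential 0.855
#>   annual precipitation reduction (median over cell-years): q25: 94.3%, q50: 93.5%, q75: 92.7%
#>   Monte Carlo: event reduction 77.4%, total reduction 92.1%
```

Reading this: the synthetic transpired fraction removes ~13% of the column
water vapor, but because the pickup relation is so steep (the exponential
fit explains far more variance than the linear one), the median-quartile
counterfactual loses ~94% of annual precipitation — a seven-fold
amplification — and the distribution-preserving Monte Carlo estimator
agrees to within a couple of points on totals. The reduction computed from
the lower quartile curve (q = 25) is the largest and from the upper
(q = 75) the smallest, so the three quartiles bracket the estimate.

```r
glance(run$summary)
#> # A tibble: 1 × 5
#>   cwv_reduction_pct annual_reduction_median_q50 event_reduction_pct_q50 n_cells
#>               <dbl>                       <dbl>                   <dbl>   <int>
#> 1              12.8                        93.5                    78.0      16
```

The pieces compose with the pipe as well:

```r
clim  <- simulate_climate(make_grid(0, 1, 0, 1, 0.25), n_hours = 17544, seed = 1)
curve <- build_quantile_curve(clim$hourly)      # 1-mm bins, >5 points, < 73 mm
cf    <- counterfactual_series(clim$hourly, curve, clim$ft)
reduction_summary(cf) |> tidy()
autoplot(curve)                                  # median line + IQR ribbon
```

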