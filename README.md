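# heatattr

Attribution of temporal trends in warm-season heat-related excess mortality
to climate change, disentangled from changing population vulnerability.

## The problem

Cities are warming, but populations are also becoming less vulnerable to
heat — in Germany and much of Europe the risk of dying on a hot day has
fallen as life expectancy has risen. Whether the heat-related death burden
is going up or down therefore depends on two opposing trends, and naive
trend estimates conflate them. `heatattr` implements a counterfactual
framework that separates the two: it asks how many warm-season deaths are
attributable to the heat added by climate change, and how that burden would
have evolved had population vulnerability (life expectancy) stayed at its
early-1990s level.

## The method

**Counterfactual temperatures.** Monthly global mean surface temperature
(GMST) anomalies are smoothed by singular spectrum analysis (120-month
window) and re-baselined to 1850–1900. Each city's annual Jun–Sep mean is
regressed on the smoothed annual GMST anomaly over 1950–2022; the
counterfactual daily series is

    T_cf(d) = T(d) − beta_city · G_smooth(month(d))

A 9-member ensemble crosses the GMST 95% CI bounds with the slope CI bounds.

**Time-varying associations.** For each city and 5-year subperiod,
warm-season daily deaths are fitted by quasi-Poisson regression with a
distributed-lag non-linear cross-basis (natural cubic exposure spline,
knots at the pooled 50th/90th percentiles; lags 0–10 days), controlling for
day of week and year-stratified seasonal splines. Each fit is reduced to
cumulative exposure–response coefficients `theta` with covariance `S`.

**Pooling and counterfactual vulnerability.** A longitudinal multivariate
mixed-effects meta-regression (maximum likelihood, city-level random
effects with unstructured covariance Psi) pools the `theta` across cities
and subperiods, with meta-predictors such as life expectancy (LE) selected
by stepwise AIC. Factual BLUPs shrink city estimates toward the pooled
prediction; counterfactual BLUPs freeze each city's LE at its first
subperiod:

    cfBLUP_ik = BLUP_ik + beta_LE · (LE_i,first − LE_ik)

**Attribution.** For every day with temperature above the minimum mortality
temperature (MMT, grid-searched over the 25th–99th percentiles),

    AN(t) = (1 − exp(−Delta(t))) · mean(deaths[t .. t+10])

with `Delta` the cumulative log relative risk versus the MMT (forward
perspective). Factual-minus-counterfactual differences give the
climate-change burden `AN_CC`/`AF_CC` and its share of the factual burden
`P_CC = 100·AF_CC/AF`, with 95% empirical CIs from 1000 Monte Carlo
coefficient draws. Annual series are summarised by per-decade OLS trends
and factual-vs-counterfactual Wilcoxon rank tests.

Because the original city mortality registers are access-restricted, the
package ships a fully specified synthetic multi-city world (15 cities,
1950–2022 temperatures, 1993–2022 overdispersed death counts with a known
exposure–lag–response surface tied to rising life expectancy) so that every
stage can be validated against known ground truth.

## Worked example

```r
library(heatattr)

world <- simulate_world(world_config(), seed = 1)
res <- run_pipeline(world, pipeline_config(
  n_mc = 1000, seed = 1, select = FALSE, meta_formula = ~le))

round(res$delta_t$period, 2)
#> mean  min  max
#> 1.78 1.53 2.03

round(res$attribution$climate$with_le$period[c("af_cc", "p_cc")], 1)
#> af_cc  p_cc
#>   1.3  78.8

sapply(res$trends[c("af_factual_with_le", "af_factual_wo_le",
                    "af_counterfactual_wo_le", "p_cc_with_le")],
       function(t) round(t$slope_decade, 2))
#>      af_factual_with_le        af_factual_wo_le
#>                   -0.15                    0.70
#> af_counterfactual_wo_le            p_cc_with_le
#>                    0.03                    3.63
```

Reading: in this synthetic world, climate change added on average 1.78 °C
(ensemble range 1.53–2.03 °C) to warm-season city temperatures over
1993–2022, and 1.3% of all warm-season deaths — 78.8% of the total
heat-related burden — are attributable to that added heat. The trend table
shows the central qualitative result: with observed life-expectancy
improvements the heat-mortality fraction *declines* (−0.15%/decade) despite
warming; had vulnerability stayed at first-subperiod levels it would have
*risen* (+0.70%/decade) — but only because of climate change, since the
same frozen-vulnerability world without climate change shows no trend
(+0.03%/decade). The climate-change share P_CC rises by 3.6 percentage
points per decade.

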