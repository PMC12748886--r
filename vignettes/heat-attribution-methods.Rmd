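---
title: "Attributing trends in heat-related excess mortality: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing trends in heat-related excess mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(heatattr)
```

# The scientific problem

Warm-season heat kills, and two opposing forces shape how many deaths it
causes over time: anthropogenic warming raises exposure, while declining
population vulnerability — strongly associated with rising life expectancy —
lowers the risk per degree. `heatattr` implements an end-to-end framework
that disentangles these forces for a panel of cities with daily all-cause
death counts and daily mean temperatures. It answers three questions: how
much warm-season warming is attributable to the observed rise in global mean
surface temperature (GMST); how much heat-related excess mortality that
warming has caused; and whether the *trend* in that burden is rising or
falling once changing vulnerability is accounted for.

The framework is a chain of five stages, each usable on its own:

1. **Counterfactual temperatures** — remove the global-warming signal from
   observed daily series.
2. **First-stage models** — city-by-subperiod quasi-Poisson regressions with
   a distributed-lag non-linear (cross-basis) term for temperature, reduced
   to cumulative exposure-response coefficients.
3. **Second-stage meta-regression** — a longitudinal multivariate
   mixed-effects model pooling those coefficients across cities and
   subperiods, with meta-predictor selection and factual/counterfactual best
   linear unbiased predictions (BLUPs).
4. **Attribution accounting** — minimum mortality temperatures (MMTs),
   attributable numbers (AN) and fractions (AF) under four scenarios
   (with/without climate change x with/without life-expectancy
   improvements), with Monte Carlo empirical confidence intervals.
5. **Trend assessment** — linear (and spline) trends of annual quantities
   and rank tests comparing factual with counterfactual trend samples.

# Counterfactual temperature construction

Monthly GMST anomalies (with their 95% CI bounds) are smoothed with
singular spectrum analysis (SSA): the series is embedded in a Hankel matrix
with a 120-month window, decomposed by SVD, and the trend is reconstructed
by diagonal averaging of the leading low-frequency components. Both the raw
and smoothed series are then re-baselined so their 1850–1900 mean is zero.

Each city's coupling to global warming is an ordinary least squares
regression of its annual June–September mean temperature on the annual mean
of the smoothed GMST anomaly over 1950–2022. The counterfactual daily
series subtracts slope x smoothed monthly anomaly from each warm-season day
(and the ten pre-season buffer days, which use their own month's anomaly).
Crossing the three GMST bounds with the three slope bounds yields a
9-member counterfactual ensemble; the central x central member is the best
estimate and the only member used for attribution point estimates, while
all members feed the trend uncertainty and rank tests.

**Design choices the literature leaves open.** The SSA component-grouping
rule is not standardised: we keep the leading components whose left singular
vectors are quasi-monotone (at most two mean-crossings across the window,
i.e. mean periodicity above the window length), with fixed-count and
variance-fraction groupings available as alternatives. GMST bounds are
smoothed separately — the reconstruction is linear given a grouping, so
ordering is preserved up to grouping differences. Slope bounds come from the
regression's t-interval with the central smoothed series as predictor; the
ensemble already crosses GMST and slope uncertainty, so we do not also vary
the predictor. The 5-year moving-average alternative (sensitivity variant)
shrinks its window symmetrically at the series edges to preserve length.

# First-stage distributed-lag models

For each city and 5-year subperiod (six blocks, 1993–2022; five 6-year
blocks as a sensitivity variant) we fit warm-season daily deaths with a
log-link quasi-Poisson model. Temperature enters through a cross-basis: a
natural cubic exposure spline with two inner knots at the 50th and 90th
percentiles of the city's pooled 1993–2022 warm-season distribution
(boundary knots at the pooled minimum/maximum — fixed across subperiods so
coefficients are comparable), tensor-combined with a lag basis over 0–10
days (natural cubic spline with an intercept and two knots equally spaced
on the log(lag+1) scale). Confounding control: day-of-week indicators and,
per calendar year, a natural cubic spline of day-of-season with two equally
spaced knots interacted with year indicators. These parameterisations are
standard for warm-season-only series; both are configurable.

Dispersion is estimated as Pearson chi-square over residual degrees of
freedom and scales the coefficient covariance; point estimates are the
Poisson ML estimates regardless of dispersion. The fit is reduced by exact
linear algebra to three cumulative exposure-response coefficients
(`theta = M eta`, `S = M V M'`, `M` summing the lag basis over lags), the
currency passed to the second stage. Aliased control columns are dropped
with a warning; a non-converged fit is excluded downstream with a warning
rather than silently pooled.

# Multivariate mixed-effects meta-regression

Units are city-subperiods; outcomes are the three reduced coefficients with
their known within-unit covariances. The longitudinal model places one
shared 3-dimensional random effect per city across its subperiods
(between-city covariance `Psi`, unstructured). Estimation is maximum
likelihood — not REML — so likelihood-ratio tests of fixed effects are valid
and AIC/BIC comparable across meta-predictor sets; `Psi` is parameterised by
its Cholesky factor and profiled out of a closed-form GLS solution for the
fixed effects (a Woodbury identity keeps every per-iteration computation at
3x3 scale). Random slopes for time and a nested outer grouping (e.g.
federal state) are implemented as alternative structures.

Meta-predictors (subperiod means per city: life expectancy, mean
temperature, temperature range, heat-alert days, mean age, % over 65) are
centred and scaled internally; predictions and reported original-scale
coefficients back-transform. The base trend model is a natural spline of
the subperiod midpoint with one knot at the study-period middle; stepwise
forward/backward selection is by AIC, with LR p-values recorded in the
trace but not used as hard gates. Life expectancy can be forced to remain
in the model, which the counterfactual BLUPs require.

Factual BLUPs shrink each unit's estimate toward the fixed-effect
prediction; their covariance uses the conditional-variance form
`X V_beta X' + Psi - Psi Z' Sigma^{-1} Z Psi`. Counterfactual BLUPs add the
factual BLUP residual to fixed-effect predictions in which each city's life
expectancy is frozen at its first-subperiod value; because the model is
linear, `cfBLUP - BLUP = beta_LE (LE_first - LE)` exactly, and the factual
covariance is carried over unchanged (the residuals add no new
uncertainty). Cochran's Q and I-squared are computed from fixed-effects GLS
residuals weighted by the within-unit covariances alone, and are reported
for both the intercept-only and the final model, since conventions differ.

# Attribution accounting

MMTs are found by grid search over the 25th–99th percentiles of the city's
daily means in 0.1-percentile steps, ties broken to the lowest temperature;
each temperature variant defines its own grid (counterfactual percentiles
for counterfactual series) while coefficients stay fixed. For every day
above the MMT, attributable deaths follow the forward perspective:
`AN(t) = (1 - exp(-Delta(t))) x mean(deaths[t..t+10])`, where `Delta` is
the cumulative log relative risk at the day's temperature versus the MMT.
The forward window truncates at September 30 (October deaths are not in the
data). AF divides seasonal AN by total warm-season deaths. Differences
between factual and counterfactual temperature scenarios give AN_CC and
AF_CC; the relative share P_CC divides AF_CC by the factual AF —
per year for trend fitting, and as a ratio of period sums for the period
aggregate (the convention is not standardised; both are reported).

Monte Carlo empirical CIs resample coefficients (1000 draws by default)
from their normal distributions, independently across city-subperiods, with
MMTs held at their point-estimate values per draw (recomputing them per
draw is a config option, off by default, chosen for stability). The
counterfactual-association draw shares the factual draw's random component,
consistent with the counterfactual BLUP being a deterministic shift of the
factual one. All-cities intervals are computed on per-draw sums.

# Trend assessment

Annual quantities are regressed on year by OLS; slopes are reported per
decade with t-intervals, and natural-spline alternatives (2–4 df) are
compared by Gaussian AIC. Differences between factual and counterfactual
city-specific trend estimates are tested with two-sided Wilcoxon rank
tests, pooling the nine ensemble members into the counterfactual sample
(15 factual vs 135 counterfactual trends). Treating ensemble members as
independent observations is statistically optimistic — the members share
the observed weather — so these p-values should be read as descriptive
strength-of-separation measures, not strict error rates.

# The synthetic world

Real city mortality registers are access-restricted, so validation runs in
a fully specified synthetic world whose every parameter is known:

* **GMST**: a logistic-plus-linear anthropogenic trend (amplitude 1.6 degC,
  midpoint 1995, width 18 years) plus AR(1) monthly noise (sd 0.12,
  coefficient 0.5), from 1850; CI bounds at plus/minus 0.05 degC. These
  values reproduce the observed magnitude of warming relative to
  pre-industrial (about 1.0–1.3 degC by 2022) and its recent pace (about
  0.2 degC per decade).
* **City temperatures** (15 cities, warm seasons 1950–2022): city base
  levels 9–12 degC, seasonal amplitude 8.5 degC peaking in late July,
  scaling slopes 1.2–2.0 (central-European summer warming amplifies global
  warming), daily AR(1) noise (coefficient 0.7, innovation sd 1.3 degC).
* **Mortality**: negative-binomial counts (variance/mean 1.3) around
  city baselines of 15–90 mean daily deaths with day-of-week effects, mild
  seasonality and a slow year trend. The true exposure-lag-response is a
  mildly U-shaped cumulative curve in the same natural-spline family as the
  fitting basis (well-specified case): a quadratic heat limb above the 60th
  percentile plus a weaker cool-side limb, so the true MMT is an interior
  minimum near the 65th–70th percentile — as in observed warm-season
  curves, and necessary for the MMT search to be a well-posed estimation
  problem. Lag weights decay exponentially (mean lag about 1.5 days) over
  lags 0–10.
* **Vulnerability**: the 99th-percentile relative risk starts at 1.45 and
  declines with each city's life-expectancy gain (0.045 log-RR units per
  year of LE, floored at log RR 0.12, i.e. RR about 1.13), with city LE
  slopes of 1.5–3.5 years per decade. The floor reflects that heat risk
  does not vanish; values below it make late-period curves so flat that
  any method's MMT and risk estimates degenerate.

What the generator deliberately does **not** emulate: spatial correlation
of weather and mortality across cities (cities are independent, so
city-average estimates are less noisy than in real panels), age structure,
harvesting/mortality displacement, data gaps, and non-climatic mortality
shocks (epidemics). Passing tests therefore demonstrate correctness of the
estimation machinery under a known data-generating process, not robustness
to every feature of real registry data.

# Numerical choices and validation problem sizes

The test suite validates each stage against independent oracles: SSA
against known noiseless trends; the cross-basis against a brute-force
double loop; fixed-effects pooling against the inverse-variance closed
form; the ML meta-regression against `metafor` on univariate cases;
BLUP limits (`Psi -> 0`, `S -> 0`) and the counterfactual-BLUP algebra
exactly; attribution against hand-computed spreadsheets and, in a
same-day-risk world (all lag mass at lag zero, matched by a zero-lag
forward window, where the identity is exact), against the closed form
`sum lambda0 (exp(Delta) - 1)`.

Simulation sizes were chosen to keep the full suite within a routine
desktop run while leaving Monte Carlo error well below the tolerances
checked: 500 replicates for scaling-slope CI coverage and for the LR-test
type-I rate, 200 for first-stage RR recovery and the attribution oracle,
100 for between-city covariance recovery, and 50 full pipeline runs for
the qualitative sign-pattern recovery (negative AF trend with LE
improvements under factual temperatures, positive without them, near-zero
without climate change, rising P_CC). The end-to-end runs use the default
world; its recovery test uses the correctly specified meta-model (`~ le`)
because in the generator vulnerability varies through life expectancy
alone — the selection ladder is exercised separately.

Optimizer settings: BFGS on the profile likelihood with relative tolerance
1e-12 and a Nelder-Mead fallback; starting values from a moment estimator
of the between-city covariance. Within-unit covariances get a 1e-12 ridge
before inversion. Ties in the MMT grid go to the lowest temperature.
Degenerate inputs error early with informative messages (all-zero
outcomes, gappy lag histories, rank-deficient designs, reference periods
outside the series).

# Known limitations

* The counterfactual removes only the GMST-scaled signal: circulation and
  aerosol-driven regional departures from global warming are not
  represented, and natural variability cannot be separated from forced
  change without climate-model ensembles.
* The Wilcoxon ensemble pooling overstates independence (see above).
* Counterfactual-BLUP covariances are copied from the factual BLUPs; any
  extra uncertainty in the frozen-LE fixed-effect prediction is ignored.
* Attribution is forward-perspective heat burden only: no cold burden, no
  backward attribution, no years-of-life-lost, no age stratification.
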