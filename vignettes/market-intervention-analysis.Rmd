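---
title: "Intervention time-series analysis of bushmeat market censuses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intervention time-series analysis of bushmeat market censuses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bushmeatTS)
```

## The problem

Urban bushmeat markets are one of the few windows onto commercial hunting
pressure in west and central African forests. A long-running daily census
of a market — every carcass recorded with species, capture method, origin,
condition and price — supports questions that snapshot surveys cannot:
did a hunting ban change the market, transiently or permanently? Is the
market growing with incomes? Has the dominant capture technology shifted
from trapping to shotguns, and which taxa paid for that shift?

bushmeatTS implements the full statistical chain for such a census on
Bioko Island's Malabo market structure: 156 monthly observations
(October 1997 – September 2010), three legislative/political market
periods (Early through March 2003, Pre-ban from April 2003, Post-ban from
the November 2007 primate hunting ban), and a handful of dated external
shocks. Because raw market censuses of this kind are typically not
public, the package ships a synthetic census generator with the same
statistical structure, so every stage is validated by parameter recovery
rather than by re-reading numbers off a table.

## The response variable

The central quantity is the **carcass rate**: carcasses recorded in a
month divided by the number of days the market was surveyed that month
(`monthly_rates()`). Species seen fewer than 75 times over the whole
study are removed first (`filter_rare()`); sporadic imports are both
biologically uninformative and prone to misidentification. A documented
single-month data loss (February 2001 in the study calendar) is repaired
by averaging the two adjacent months (`impute_gap()`); longer gaps are an
error by design — the package refuses to chain imputations.

## The intervention model

Market shocks are modelled on the square-root scale of the carcass rate
(a variance-stabilising transform for count-like rates):

$$ z_t = \mu + \sum_j m_t^{(j)} + N_t $$

where each intervention response $m_t$ is built from a **step** (a
permanent shift $w_S S_t$, with $S_t$ the unit step at the event month),
a **pulse** (a momentary deviation $w_P P_t$), and optionally a geometric
**lag** $(1 - \delta B)^{-1}$ with backshift operator $B$, which spreads
the pulse over subsequent months:

$$ m_t = w_S S_t + \frac{w_P}{1 - \delta B} P_t
       = w_S \mathbf{1}(t \ge e) + w_P\, \delta^{t-e}\, \mathbf{1}(t \ge e). $$

`transfer_response()` evaluates this by the exact recursion
$m_t = \delta m_{t-1} + w_P P_t$, so the defining difference equation
holds to machine precision. The hunting-ban pattern — an immediate crash
followed by a slow rebound to a permanently higher level — is a negative
pulse plus a positive step with $\delta$ close to 1. The lag acts on the
pulse by default (`lag_on = "pulse"`); attaching it to the step instead
is supported for saturating-ramp shapes.

The noise $N_t$ is a seasonal autoregression,
ARIMA$(2,0,0)\times(1,0,0)_{12}$ by default: two regular AR terms plus
one seasonal AR term at lag 12, Gaussian innovations. `sarima_fit()`
estimates it by exact Gaussian maximum likelihood through the
state-space prediction-error decomposition, initialised from conditional
sums of squares; standard errors come from the inverse observed
information.

`arimax_fit()` estimates noise and intervention parameters jointly. Step
and pulse weights enter the likelihood linearly, so the lag weight is the
only non-linear parameter: it is profiled out — a coarse grid plus
minimisation on the conditional-sum-of-squares criterion to locate it
(initialisation only), then golden-section refinement of the exact
profile likelihood. The reported fit therefore maximises the full
likelihood over every parameter. Reported AIC counts the profiled lag
weight, which the inner likelihood engine does not see. Standard errors
are conditional on the profiled lag by default (`se = "conditional"`,
with a profile-curvature SE for the lag itself); `se = "joint"` computes
the full observed-information matrix by numerical differentiation of
fixed-parameter likelihood evaluations.

Model reduction follows the conventional backward-elimination rule
(`prune_nonsignificant()`): repeatedly drop the least significant
component with $|\hat w|/\mathrm{SE} < 1.96$ and refit, until every
remaining component survives. Residual adequacy is summarised by the
Ljung–Box portmanteau statistic (`ljung_box()`), referred to a
chi-square with $L - (p + P)$ degrees of freedom by default ($L = 12$
lags minus the fitted AR and seasonal-AR parameter count).

Because the model lives on the sqrt scale, an intervention's practical
effect is reported by squaring the structural (noise-free) fitted values:
`percent_change()` returns $100(\hat y_{t_0} - \hat y_{t_1})/\hat y_{t_0}$
with a delta-method confidence interval over the mean, weight and lag
estimates, or a parametric bootstrap from their joint sampling
distribution. The two intervals agree closely when the weight estimates
are well conditioned; the bootstrap is preferable near the boundary
$\delta \to 1$.

## Decomposition, trends, associations

**Decomposition.** `decompose_rates()` splits a monthly series additively,
$Y_t = T_t + S_t + E_t$: the trend is a first-order loess over 24 monthly
points, the seasonal component a second-order loess of the residuals over
6 points, and the remainder is defined by subtraction, so additivity is
exact by construction. Loess here always means: at each point, a weighted
least-squares polynomial over the $q$ nearest points with tricube weights
on scaled distance, no robustness iterations; the span is given as a
point count, not a fraction. The 6-point residual smooth is the literal
recipe for these data; it inevitably leaves some month-to-month error in
$S_t$, with $E_t$ absorbing the rest. An STL-style alternative that
smooths each calendar-month subseries (`seasonal_method = "cycle"`) is
provided as a cross-check and agrees with the default to well under 20%
RMS on sinusoidal test signals. Trend regressions use the
deseasonalized series $T_t + E_t$; income regressions use the denoised
series $T_t + S_t$.

**Per-period trends.** `fit_period_trend()` regresses deseasonalized
rates on serially numbered months (numbered 1–156 over the whole study,
never restarted within a period — the midpoint of a later period is a
large month number on purpose). The quadratic term is retained only when
a partial F-test at $\alpha = 0.05$ says the linear model is
significantly worse. Slopes of different taxa are made comparable by
`normalize_slope()`: division by the SD ratio of taxon to total series
(default; slightly conservative for uncommon taxa) or by the taxon's
fraction of the total market rate. The SD normalization uses the raw
(not deseasonalized) series by default; both inputs are accepted.
"Significantly different" between periods is operationalised in
`compare_slopes()` as a Welch-type z-test on the slope difference, with
CI non-overlap reported alongside as the conservative companion.

**Associations.** `gls_anova()` is an iterative feasible GLS two-factor
ANOVA of log rates on capture method and period with one residual
variance per method-by-period cell (six variances; a 2 + 3 multiplicative
per-factor-level variant is available, since "a different variance per
factor level" admits both readings). Wald F statistics use denominator
degrees of freedom $N - p$; with 156 months and two methods that is
$F_{2,306}$ for the interaction. Zero rates ahead of the log are offset
by half the smallest positive observed rate; no offset is added when all
rates are positive. `bootstrap_correlation()` gives the trap–shotgun
Pearson correlation with a percentile bootstrap interval over paired
month resampling (BCa optional). `proxy_regression()` regresses denoised
rates on a monthly income proxy (an oil spot price where national income
statistics are unreliable) per stratum and period; the "All" row pools
the observations of all periods rather than averaging per-period fits.

## The synthetic census generator

`generate_census()` draws a record-level census from a
`scenario_config()`. Its defaults emulate the study conditions:

* **Window and periods:** 156 months from October 1997; period
  breakpoints April 2003 and November 2007.
* **Market days:** 26 potential days per month minus a
  Binomial(4, 0.5) dropout, giving a mean of 24 surveyed days
  (the study averaged ~24.1 = 3,758 days over 156 months) for a
  Monday–Saturday market with occasional Sunday activity.
* **Counts:** daily carcasses per species are Poisson with mean
  $\lambda_{s,t} = \max(0,\ \text{baseline} + \text{cumulative trend})
  \times (1 + a\cos(2\pi(t - \text{phase})/12))$, amplitude $a < 1$ so
  rates stay non-negative; negative extrapolated rates truncate at zero
  (rates are physical counts). The census protocol does not constrain
  the count law, so Poisson is the documented default and a
  negative-binomial option (`count_model = "nbinom"`) covers
  overdispersion.
* **Interventions:** events perturb targeted taxon groups additively on
  the square-root scale, $\lambda' = (\max(0, \sqrt{\lambda} + m_t))^2$
  — the reading under which generator and estimator are conjugate, so
  recovery experiments test the fitter against its own generating
  process.
* **Attributes:** capture method is Bernoulli with a period-specific
  shotgun probability (the trap-to-shotgun transition), origin is
  Bernoulli island-vs-import, condition follows the study's observed
  fresh/smoked/alive frequencies (0.819/0.126/0.055), and price is
  log-normal around a mass-based level.
* **Determinism:** the scenario seed fully determines the output;
  pipeline stages draw from named substreams of one root seed.

`generate_sqrt_series()` simulates the sqrt-scale model directly
(SARIMA noise plus transfer responses) with a burn-in of 120 months —
ten seasonal cycles — so the noise starts from its stationary
distribution. The demonstration scenario (`default_scenario()`) uses
eleven species whose baselines scale the market from roughly 30 to 90
carcasses per market day across the periods, one deliberately rare
species to exercise the rarity filter, a February 2001 data-loss month,
and the four study-pattern events. Two of the default event weights
share the value 3.037 (the 2003 pulse and the 2007 step); they are
independent parameters that happen to share a printed value in the
published estimates used as defaults.

What the generator does **not** emulate: spatial hunting catchments,
hunter behaviour, price dynamics, observer error or double counting, and
import-volume trends. Passing recovery tests therefore demonstrates the
estimation machinery is correct for data satisfying the model's
assumptions, not that real market data satisfy them.

## Validation design and problem sizes

The package validates itself at these fixed problem sizes (chosen once
to balance Monte-Carlo precision against suite runtime):

* Noise-model recovery: 500 simulated series of length 121 from the
  published coefficients $\phi = (0.343, 0.301)$, $\Phi = 0.208$.
* Joint intervention recovery: 200 simulated series of 156 months from
  the full published four-event configuration, with innovation SD 0.323
  (the published residual RMSE) and sqrt-scale level $\mu = 2$
  ($\approx$ the early-period primate rate of ~4 carcasses/day).
* Backward-elimination behaviour: 40 replicates with a fifth,
  truly-null event added (a May 2000 event with zero weight, mirroring
  the event the published analysis discarded).
* Slope-interval coverage: 1,000 simulated 55-month periods; GLS
  interaction size: 1,000 replicates at the study's cell sizes
  (66/55/35 months per period, two methods); bootstrap coverage: 500
  replicates at $n = 156$, $\rho = -0.86$.

## Numerical choices and known limitations

* Exact-ML autoregressive estimates carry the classic $O(1/n)$
  downward finite-sample bias: at $n = 121$ the mean estimate of
  $\phi_2$ sits about 0.02–0.04 below truth. This is a property of ML
  estimation at this series length, not of the implementation; recovery
  experiments that average estimates across replicates see it.
* The final-event step and a slowly decaying pulse ($\delta \approx
  0.95$ with only ~35 post-event months) are nearly collinear; their
  estimates are heavy-tailed and anticorrelated across replicates, and
  conditional standard errors understate the uncertainty. The joint
  observed-information option and the parametric bootstrap are the
  honest alternatives.
* The lag profile likelihood can be multimodal near $|\delta| \to 1$;
  the coarse grid plus bracketed refinement handles the configurations
  exercised here, and the grid is user-extensible.
* `arimax_fit()` supports at most one lagged intervention per fit;
  moving-average noise terms are accepted structurally but not exercised
  by the validation suite; model orders are fixed by the analyst, never
  selected automatically.
* Backward elimination inherits the usual caveat of stepwise selection
  under collinearity: when a genuinely weak step is eliminated, a nearby
  null step can absorb its role and survive. Null *pulses* are immune
  (single-month components are orthogonal across months); null steps
  adjacent to weak true steps are not. Interpret surviving components
  jointly, not in isolation.
* The FGLS ANOVA estimates six variances from cell residuals; with
  few months per cell its interaction test can run slightly liberal,
  which the size simulation bounds at the study's cell sizes.
* Imputation handles isolated single-month gaps only, matching its one
  documented use.
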