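# bushmeatTS

Statistical pipeline for long-running bushmeat-market carcass censuses,
built around the 13-year monthly structure of the Malabo (Bioko Island)
market: 156 months, three legislative market periods, and dated external
shocks (a coup attempt, conservation roundtables, hunting laws, a primate
trade ban). The package is aimed at conservation scientists and
quantitative ecologists who monitor wildlife-trade markets and need to
ask: did an intervention change the market, transiently or permanently —
and is the market tracking income?

## What it computes

* **Carcass rates** — records filtered for rarity (< 75 study-wide
  records), aggregated to carcasses per market day per month, with
  documented single-month gaps imputed from neighbours, and a
  species/group market summary (counts, biomass, percentage shares).
* **Intervention (transfer-function) model** — on the square-root scale,

  $$z_t = \mu + \sum_j \Big( w_{S,j} S_t^{(j)} +
      \tfrac{w_{P,j}}{1 - \delta_j B} P_t^{(j)} \Big) + N_t,$$

  where $S_t$/$P_t$ are unit step/pulse functions at event months, $B$
  the backshift operator, and $N_t$ a seasonal
  ARIMA$(2,0,0)\times(1,0,0)_{12}$ autoregression. Estimation is exact
  Gaussian maximum likelihood with the lag weight $\delta$ profiled out;
  non-significant components can be pruned by backward elimination;
  effects are reported as original-scale percentage changes with
  delta-method or parametric-bootstrap intervals.
* **Decomposition** — additive $Y_t = T_t + S_t + E_t$ via first-order
  loess over 24 monthly points (trend) and second-order loess of the
  residuals over 6 points (seasonal), remainder by subtraction.
* **Per-period trends** — quadratic-or-linear regression of
  deseasonalized rates on serially numbered months, midpoint slopes with
  t-based 95% CIs, slopes normalized across taxa by SD ratio or market
  fraction, and pairwise period comparisons.
* **Associations** — heteroscedastic two-factor GLS ANOVA (capture
  method x period, one residual variance per cell), trap-shotgun
  bootstrap correlation, and income-proxy (oil price) regressions per
  stratum and period.
* **Synthetic census generator** — seed-deterministic daily records
  (species, method, origin, condition, price) and sqrt-scale series with
  the exact structure the estimators assume, used for parameter-recovery
  validation throughout.

## Worked example

Simulate a sqrt-scale primate series from the four study-pattern events
and refit it:

```r
library(bushmeatTS)

events <- list(
  intervention_spec("1998-02", pulse = -1.357),
  intervention_spec("2002-03", step = 0.457, pulse = -0.625),
  intervention_spec("2003-11", step = -1.001, pulse = 3.037),
  intervention_spec("2007-11", step = 3.037, pulse = -5.202, lag = 0.945)
)
noise <- sarima_spec(ar = c(0.343, 0.301), seasonal_ar = 0.208,
                     sd = 0.323, mean = 2)
z <- generate_sqrt_series(noise, events, n_months = 156, seed = 42)
fit <- arimax_fit(z, interventions = events)
fit
#> Intervention model: ARIMA(2,0,0)x(1,0,0)_12 noise, 4 intervention(s)
#> # A tibble: 3 x 5
#>   component `02/1998`      `03/2002`      `11/2003`      `11/2007`
#>   <chr>     <chr>          <chr>          <chr>          <chr>
#> 1 step      ---            0.653 (0.122)  -0.992 (0.125) 3.631 (0.212)
#> 2 pulse     -1.281 (0.271) -0.152 (0.281) 2.691 (0.271)  -5.271 (0.317)
#> 3 lag       ---            ---            ---            0.960 (0.013)
#> loglik -22.123  AIC 70.25  RMSE 0.2783
```

Each cell is `estimate (SE)` for one event: the 11/2007 pattern — large
negative pulse, positive step, lag near 1 — is the crash-and-rebound
signature of a trade ban. The refit recovers the generating pattern;
the final event's step and lag estimates trade off against each other
(a slowly decaying pulse is nearly collinear with a step over a short
post-event window), which is why this realization's step sits above its
generating value of 3.037 — see the methods vignette's discussion of
this limitation. The implied original-scale change across
the ban month, and the residual diagnostic:

```r
percent_change(fit, "2007-10", "2007-11")
#> implied rate decline 97.39% (95% CI 88.12, 106.66)
ljung_box(fit$residuals, lags = 12, fitdf = 3)
#> Ljung-Box Q = 9.69 on 9 df, p = 0.38
```

A full record-level analysis runs through the pipeline driver:

```r
cfg <- read_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "bushmeatTS"))
report <- run_pipeline(cfg, out_dir = "demo-run")
```

which writes every intermediate table (monthly rates, intervention
parameters and fitted values, decomposition, per-period slopes, ANOVA,
bootstrap correlation) as CSV plus a JSON run report; identical
configuration and seed give identical outputs. The packaged species
reference is available as `species_reference()`, and
`market_summary(species_reference())` reproduces the study-wide
counts/biomass summary (196,892 carcasses; rodents 41.09% of counts;
duikers 48.58% of biomass).

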