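# ardlfire

Dynamic simulated ARDL modelling of fire–climate time series.

## The problem

Monthly grassland burned area and the climate variables that drive it
(temperature, humidity, precipitation, wind speed, sunlight, fire carbon
emissions) are typically *nonstationary*: their means drift, so ordinary
least squares on the raw series produces spurious regressions. The
autoregressive distributed lag (ARDL) bounds-testing framework handles this
by rewriting the regression in error-correction form,

```
Δy_t = α0 + θ0·y_{t−1} + Σ_k θk·x_{k,t−1}
     + Σ_i αi·Δy_{t−i} + Σ_{k,j} β_{k,j}·Δx_{k,t−j} + ε_t
```

where all variables are natural logs of the monthly series. The lagged
levels carry the long-run (cointegrating) equilibrium: the **long-run
elasticity** of driver *k* is `−θk/θ0` (percent change in burned area per
percent change in the driver at equilibrium), and `θ0` — reported as
**ECM(−1)** — is the fraction of any disequilibrium corrected each month
(negative for a converging system). A joint F-test on the lagged levels
("bounds test") decides whether a long-run relationship exists at all,
using lower/upper critical bounds for the all-I(0) and all-I(1) cases.
Counterfactual climate-shock experiments are run by drawing the coefficient
vector from its estimated sampling distribution and iterating the
error-correction recursion, which yields full uncertainty bands for the
burned-area response.

The package is aimed at fire ecologists and time-series analysts who want
this workflow end to end: integration-order testing (ADF and
Phillips–Perron with embedded finite-sample critical values), VAR lag
selection, error-correction estimation, bounds cointegration testing,
long-/short-run elasticities, stochastic shock simulation,
CUSUM/CUSUMSQ stability tests and residual diagnostics — plus a seeded
synthetic-data generator with known ground truth so every stage is
verifiable without access to proprietary fire records.

## Worked example

Generate a synthetic cointegrated fire–climate system at the study
conditions (216 months, adjustment speed −0.611/month, long-run wind
elasticity 20.81), fit the error-correction model, test for cointegration
and simulate a one-standard-deviation wind shock:

```r
library(ardlfire)
sys <- generate_ecm_system(dgp_spec(seed = 42))
ds  <- sys$data                       # log-scale fire_ts, 2001-01..2018-12

fit <- fit_ecm(ds, ecm_spec())        # ARDL(1,1,1,1,1,0,1)-style orders
bounds_f_test(fit)
#> Bounds cointegration test: area_burned = f(cem, rel_humidity, t_min, t_max, precip, sunlight, wind)
#>   F = 18.703 on 8 level terms (k = 7); bounds at 5%: I(0) 2.32, I(1) 3.50
#>   decision: cointegrated

long_run_coefficients(fit)
#> Long-run elasticities (-theta_k / theta_0):
#>     regressor elasticity     se       z      p
#>           cem     2.7673 0.5990  4.6202 0.0000
#>  rel_humidity     0.6589 0.7718  0.8537 0.3933
#>         t_min    -0.1132 0.6331 -0.1788 0.8581
#>         t_max     8.3162 0.6297 13.2073 0.0000
#>        precip     0.9694 0.4304  2.2521 0.0243
#>      sunlight     3.7521 0.9697  3.8693 0.0001
#>          wind    20.3929 0.9787 20.8366 0.0000
#> theta0 = -0.6932 | R2 0.558 adj-R2 0.507 SSR 18.34 DW 1.941
```

The fitted wind elasticity (20.39 ± 0.98) recovers the generator's truth of
20.81: a 1% increase in wind speed raises equilibrium burned area by about
20%. `ECM(−1) = −0.693` means roughly two thirds of any disequilibrium is
corrected within a month. The bounds F statistic (18.7) is far above the
upper 5% bound (3.50), so a level relationship is confirmed.

```r
sim <- simulate_response(fit, ds, shock_scenario("wind", seed = 1))
sim
#> Dynamic ARDL simulation: +1 sd shock to wind at period 10 (horizon 20, 5000 draws kept)
#>   mean level: pre-shock -6.300 -> terminal -3.321 (shift 2.980 log units)
```

The permanent +1 SD wind shock (0.146 log units here) shifts mean log
burned area by 2.98 ≈ 20.4 × 0.146 — the simulation converges to exactly
the long-run elasticity algebra, with nested 75/90/95% bands in
`sim$bands`. The whole workflow (unit roots → lag selection → eight-model
rotation → bounds → elasticities → diagnostics → simulations) runs as one
call via `run_pipeline(pipeline_config(...))`.

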