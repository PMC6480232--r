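# plumekrig

Inverse emission estimation and residual-kriging concentration maps for
sparse low-cost PM2.5 sensor networks.

Community networks of low-cost optical PM2.5 monitors report period-averaged
concentrations at a few dozen sites. `plumekrig` turns those measurements
into two products that the raw network cannot provide:

* **emission rates for prescribed source regions** — border line sources and
  an interior area source — with bootstrap confidence intervals, and
* **finely resolved concentration maps** whose large-scale structure comes
  from a dispersion model rather than from interpolation alone.

It is aimed at air-quality researchers and practitioners working with
community monitoring data in source-dominated basins (agricultural valleys
ringed by desert, lakebed and cross-border sources are the motivating case).

## Method

For every non-calm hour (friction velocity u* > 0.1 m/s), steady-state
Gaussian plume kernels — finite line sources at arbitrary wind angle,
integrated adaptively, and polygonal area sources decomposed into
wind-perpendicular lines — are run with **unit emissions** and averaged into
a transfer matrix *T*, where *T<sub>ik</sub>* is the concentration at
receptor *i* per unit emission of source category *k* (µg/m³ per ton/day).
Category rates *E* solve the non-negative least-squares problem

&nbsp;&nbsp;&nbsp;&nbsp;min<sub>E ≥ 0</sub> ‖ T E − c<sup>obs</sup> ‖²,

i.e. observed concentrations c<sup>obs</sup><sub>i</sub> = Σ<sub>k</sub>
E<sub>k</sub> T<sub>ik</sub> + ε<sub>i</sub>. Uncertainty comes from a
residual bootstrap (resample ε with replacement, refit, take the 2.5/97.5
percentiles). Maps are built by **residual kriging**: the dispersion model
with fitted rates gives the mean field on a regular grid, and the
model−observation residuals are simple-kriged (exponential variogram, known
mean 0) and added back. Model skill is summarized by the fraction of sites
within a factor of 2, the geometric standard deviation s<sub>g</sub> of the
observed/modeled ratio, r², and leave-one-out cross-validation against
plain simple kriging.

Because no sensor-network data ship with the package, `valley_scenario()`
generates a fully specified synthetic valley (11 border line sources in 4
categories + 1 area source, 20 receptors at "town" locations, a
westerly-dominated wind rose with a day/night stability cycle, multiplicative
sensor noise) so every stage is testable end to end. The methods vignette
(`vignettes/residual-kriging-pipeline.Rmd`) documents the model, the
numerical choices and the generator's realism limits.

## Worked example

Twelve receptors, 120 hours of synthetic meteorology, 15% sensor noise:

```r
library(plumekrig)
sc  <- valley_scenario(seed = 1, n_receptors = 12, n_hours = 120)
tm  <- build_transfer_matrix(sc$sources, sc$receptors, sc$met)
obs <- make_observations(tm, sc$E_true, noise_sd = 0.15, seed = 2024)
nnls_fit(tm, obs)
#> Emission rates (tons/day):
#> West Desert  Salton Sea East Desert      Mexico      Valley
#>       1.302       0.959       0.000       3.648      13.527
#> RSS: 5.359  KKT: TRUE
bootstrap_ci(tm, obs, B = 1000, seed = 99)
#> Residual bootstrap, 1000 replicates
#>      category  rate ci_low ci_high ci_range_normalized
#> 1 West Desert  1.30   0.00    9.58                7.36
#> 2  Salton Sea  0.96   0.00    6.02                6.28
#> 3 East Desert  0.00   0.00   20.23                  NA
#> 4      Mexico  3.65   3.03    4.89                0.51
#> 5      Valley 13.53   2.86   15.10                0.90
performance_report(obs, nnls_fit(tm, obs)$fitted)
#>    n fraction_within_2 fraction_within_1.5       sg        r2
#> 1 12                 1                   1 1.126494 0.7094717
```

Reading this: the valley interior dominates the fitted emissions
(13.5 tons/day against a configured truth of 12.4), the Mexico border
category is tightly identified because several receptors sit in its plume
path (CI 3.0–4.9 vs truth 2.8), while East Desert is unidentifiable under
westerly-dominated winds — its rate collapses to the non-negativity boundary
with an uninformative interval, exactly the behavior expected of this
inverse problem. All twelve fitted concentrations fall within a factor of
1.5 of the observations (s<sub>g</sub> = 1.13). A 12-receptor, 96-hour fit
is deliberately small; the package defaults (20 receptors, 720 non-calm
hours) identify the four non-eastern categories more stably.

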