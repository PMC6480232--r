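---
title: "From a sparse PM2.5 sensor network to emission rates and concentration maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a sparse PM2.5 sensor network to emission rates and concentration maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumekrig)
```

## The problem

A community network of low-cost optical PM2.5 monitors gives period-averaged
concentrations at a few dozen points in an air basin. Two questions follow:
how much do the surrounding source regions emit, and what does the
concentration field look like *between* the monitors? `plumekrig` answers
both with a four-stage pipeline:

1. **Unit-emission dispersion.** Prescribed source regions — border line
   sources and an interior area source — are run through a steady-state
   Gaussian plume model with a unit emission rate, hour by hour, and the
   hourly couplings are averaged over the fitting period into a transfer
   matrix $T$, where $T_{ik}$ is the concentration at receptor $i$ per unit
   emission rate of source category $k$ (µg/m³ per ton/day).
2. **Inverse emission estimation.** Category rates $E$ solve
   $\min_{E \ge 0} \lVert T E - c^{obs} \rVert^2$ — non-negative least
   squares, because emission rates cannot be negative and near-collinear
   categories would otherwise trade unbounded positive and negative rates.
3. **Uncertainty.** A residual bootstrap: fitted residuals are resampled
   with replacement across receptors, added to the fitted concentrations,
   clipped at zero, and refitted; the 2.5 and 97.5 percentiles of the
   replicate rates form the 95% interval.
4. **Residual kriging.** The dispersion model with fitted rates provides the
   mean concentration field on a regular grid; the model–observation
   residuals are interpolated by simple kriging with known mean zero and
   added back. Where sensors are dense the map honors the data; far from
   sensors it falls back to the physically structured mean field instead of
   a flat statistical mean.

## The dispersion kernel

For one met hour, the concentration per unit emission rate of a ground-level
point source at crosswind offset $y$ and downwind distance $x$ is the
standard reflected Gaussian plume

$$\chi(x, y, z) = \frac{f_y(y;\sigma_y)}{U}
  \sum_{n=-N}^{N}\big[\phi_z(z - 2 n z_i - h) + \phi_z(z - 2 n z_i + h)\big],$$

with $f_y$ and $\phi_z$ normal densities of scale $\sigma_y(x)$ and
$\sigma_{z,\mathrm{eff}}(x) = \sqrt{\sigma_z(x)^2 + \sigma_{z0}^2}$, $U$ the
reference-height wind speed, $z_i$ the mixing height, and $N = 2$ image
pairs representing reflections at the ground and at the mixing lid. When
$\sigma_{z,\mathrm{eff}} > 1.6\, z_i$ the vertical factor switches to the
well-mixed limit $1/z_i$; with two image pairs the two branches agree to
about 0.03% at the switch point, so the kernel is effectively continuous and
monotone in $\sigma_{z0}$. Upwind contributions, and contributions from
sources closer than 1 m along-wind, are zero — a steady-state plume has no
meaning at zero travel distance.

Plume spreads come from a pluggable scheme; the default is the Briggs rural
(open-country) interpolation keyed to a Pasquill class derived from the
Monin–Obukhov length with fixed Golder-style boundaries on $1/L$
(A for $1/L \le -0.07$, D for $|1/L| \le 0.002$, F for $1/L \ge 0.02$, in
1/m). The class-D spread $\sigma_y(1000\,\mathrm{m}) \approx 76.3$ m. A
micrometeorology-based scheme can be swapped in with
`register_sigma_scheme()` without touching the rest of the pipeline.

**Finite lines and areas.** A line source at arbitrary wind angle is the
line integral of the point kernel, taken per unit *total* line emission
(the category rate is spread along the border). The integrand's scales
($\sigma_y$, $\sigma_z$) all grow with the along-wind distance from the
receptor, so integration points are placed log-spaced in that distance, in
two half-meshes graded toward the receptor and toward the line's upwind
end (where the scaled crosswind offset can attain its minimum), with
2-point Gauss–Legendre nodes per cell. The cell count doubles until every
receptor's value changes by less than `line_tol` (default 1e-3 relative);
receptors already converged drop out of further refinement, and couplings
below 1e-9 of the largest one are not refined further — they are
physically irrelevant to the period average. A wind-perpendicular line is
a single crosswind slice whose integral is exact (normal CDF difference).

An area source is decomposed into such crosswind slices (the crosswind
integral within a slice is exact), log-spaced in upwind distance per
receptor, with the slice count doubled until the relative change is below
`area_tol` (default 1e-2). Against a dense 2-D quadrature oracle the
decomposition agrees to ~0.05% at tight tolerance; against a
2,000,000-point 1-D reference the error is below $10^{-4}$.

## Units and conventions

Coordinates are planar projected meters (x east, y north); wind directions
are meteorological (degrees FROM, clockwise from north), so a westerly wind
(270°) transports toward $(+1, 0)$. Emission rates are short tons per day
(1 ton/day = 10.49982 g/s), matching the regional inventory unit; transfer
entries are µg/m³ per ton/day. Receptors default to z = 2 m. Hours with
friction velocity $u_* \le 0.1$ m/s are calm and excluded (strict
inequality). Sensors enter an annual fit only with ≥ 6 operational months
(a month is operational when ≥ 75% of its hours report), and a monthly fit
only with ≥ 100 hours in that month.

## The synthetic valley

No real network data ship with the package, so `valley_scenario()` builds a
fully specified stand-in with the statistical structure the pipeline
assumes: a 40 × 80 km agricultural valley; 11 border line sources in four
categories (3 west-desert, 1 northern lakebed edge, 3 east-desert, 4
southern international border, all with $\sigma_{z0} = 10$ m) plus the
valley itself as one interior area source; default true rates of 2.8, 3.5,
0.34, 2.8 and 12.4 tons/day for West Desert, Salton Sea, East Desert,
Mexico and Valley — magnitudes taken from a comparable real inventory; 20
receptors jittered around 14 "town" anchors that mimic a community
network's geography (a border city and southern corridor, west- and
east-side towns, northern towns, two near-shore sites, a west-edge
community); and 900 hourly met records with a westerly-dominated five-sector
wind rose, unstable deep days and stable shallow nights, and exactly 20%
calm hours — leaving 720 non-calm hours, the fitting period. Observation
noise is multiplicative lognormal (σ = 0.15 by default), the signature of
optical sensors whose relative scatter dominates; an optional spatially
correlated additive field (exponential variogram) exercises residual
kriging. Everything is byte-reproducible from one seed.

The receptor geography matters scientifically: with receptors in a few
tight clusters the East Desert transfer column is nearly collinear with the
Valley column (correlation ≈ 0.94) and its unstable estimates bias the
Valley rate; the spread network conditions the transfer matrix (condition
number ≈ 21 instead of ≈ 139) the way a real, deliberately sited network
does. Even so East Desert remains unidentifiable — its peak contribution is
below 1% of the mean concentration under westerly-dominated winds — which
reproduces a known feature of this inverse problem rather than a defect.

What the generator does *not* emulate: instrument drift and humidity
response, diurnal emission profiles, terrain steering, calm-hour
accumulation, or model-structural error in the spread curves. Passing tests
therefore demonstrate internal correctness and statistical calibration of
the pipeline under its own assumptions, not field accuracy.

## Numerical and statistical choices

* **NNLS** is solved by the Lawson–Hanson active-set method; every fit is
  checked against its Karush–Kuhn–Tucker certificate (positive rates have
  zero normalized gradient, zero rates non-negative gradient, tolerance
  1e-8).
* **Bootstrap** resamples residuals with replacement (the standard residual
  bootstrap), clips pseudo-observations at zero, and uses percentile
  intervals. A designed simulation study shows per-category coverage of
  about 0.88–0.95 at 20 receptors under 15% multiplicative noise; part of
  the shortfall from 0.95 is structural — a common multiplicative level
  shift is absorbed into the fit and leaves no trace in the residual pool.
* **Variograms** default to the isotropic exponential family,
  $\gamma(h) = c_0 + c_1 (1 - e^{-h/a})$ (classic range parameter $a$),
  fitted by weighted least squares with pair-count weights from a fixed
  multi-start grid, so fits are deterministic. Single-realization
  estimation of $c_0$ and $a$ from ~200 points is intrinsically noisy
  (sampling spread well above 25% for the nugget even with nested
  close-pair sampling designs); the sill is estimated much more stably.
  Residuals are kriged with known mean zero (they are least-squares
  residuals); raw-observation maps use the arithmetic mean of the
  observations.
* **Degenerate inputs**: duplicate kriging locations raise an error naming
  the rows; an all-zero empirical variogram yields a pure-nugget-zero model
  with a warning and kriging then returns the mean; an all-zero transfer
  column yields a zero rate with a degeneracy warning; negative map values
  are floored at zero last, with the count logged.
* **Problem sizes**: the bundled checks run the full 720-non-calm-hour,
  20-receptor scenario for inversion and coverage (100 noise replicates,
  B = 500), a 180-hour subset for the five-point $\sigma_{z0}$ sweep, and a
  2000 m demonstration grid (inset one cell from the domain boundary, where
  the border line sources themselves sit) with a 3× thinned met series for
  maps — sizes chosen so the whole suite completes in minutes while leaving
  every mechanism at full strength.

## Known limitations

Straight-line steady-state transport is not credible beyond ~10 km, an
inherited limitation of the plume formulation; source–receptor relations at
longer ranges should be read qualitatively. Release heights for border
lines default to ground level and emissions are time-constant within a
fitting period. The r² statistic is the squared Pearson correlation, which
matches how low r² values co-occur with low observed variance; an
$1 - SSE/SST$ definition would differ for biased fits. The LOOCV comparison
evaluates interpolation skill across sites for a single period; with ~20
sites its variogram is fitted once on all residuals and held fixed across
folds for stability.
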