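---
title: "Spatio-temporal kriging of mobile air-quality sensor data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal kriging of mobile air-quality sensor data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stkrige)
```

## The problem

A handful of low-cost gas sensors ride city trams along fixed routes,
sampling ozone every few tens of seconds; one regulatory fixed station
provides an accurate hourly reference series. The goal is an hourly
concentration map of the whole city, with uncertainty, using nothing but
the pollution data itself — no land-use covariates, no dispersion model.
`stkrige` implements that pipeline: per-sensor calibration against the
station, spatio-temporal variography, three kriging predictors plus an
inverse-distance-weighting (IDW) baseline, scenario-based
cross-validation, and gridded prediction/variance maps. A synthetic
campaign generator stands in for real tram data so that every stage is
testable end to end.

## Model

Concentrations are a random function $Z(x, t)$ on
$D = \mathbb{R}^2 \times \mathbb{R}_+$, observed at the tram sample
points. Working conventions: planar metres east/north of a local origin
(lat/lon inputs are projected on read with a city-scale
azimuthal-equidistant projection), time in seconds since the campaign
epoch, values in µg/m³ once calibrated.

**Calibration.** Each sensor $i$ reports a raw signal $X_i(x,t)$ related
to the truth by a linear distortion. With $F(t)$ the station series
(linearly interpolated between hourly nodes and never extrapolated), the
coefficients are estimated once per sensor by ordinary least squares in

$$F(t) = a_i + b_i X_i(x,t) + \varepsilon,$$

and applied as $Z_i = a_i + b_i X_i$. Two properties of this scheme are
worth knowing. First, it is consistent when $\varepsilon$ is regression
error on the reference side; when the *raw signal* itself is noisy, or
when the sensor genuinely sees spatial variability the station does not,
OLS attenuates $b_i$ toward zero and pulls every sensor's mean toward
the station mean (errors in variables). The package implements the
scheme as is — the attenuation is a property of the method, visible on
the synthetic campaign, and deliberately not "fixed". Second, calibrated
values may be negative (a linear map can undershoot); they are kept,
since clamping would bias the kriging mean.

**Variogram.** Dependence is modelled through the semivariogram only
(no covariance-function estimation), with a *metric* spatio-temporal
structure

$$\gamma(h, u) = \gamma_{\mathrm{joint}}\!\left(\sqrt{h^2 + (K u)^2}\right),$$

where $h$ is the spatial lag (m), $u$ the temporal lag (s) and $K$
(m/s) the spatio-temporal anisotropy — the number of space units
equivalent to one time unit. Three bounded joint families are provided:
spherical, exponential (range = practical range, factor 3 in the
exponent, so "range" is comparable across families) and bounded-linear
(linear to the range, flat beyond — the only consistent reading of a
"linear" model that reports a sill). $\gamma(0,0) = 0$ exactly; the
nugget is the limit from above.

The empirical surface accumulates $(z_i - z_j)^2/2$ over all pairs
within the lag limits into an equal-width 2-D bin grid (default
12 × 12). The spatial limit defaults to half the maximum pairwise
distance, beyond which pair counts decay and the estimate loses
robustness. The temporal limit is a configuration value;
`suggest_temporal_cutoff()` mechanises the step-by-step search for the
lag at which the temporal margin stops increasing (relative slope below
5% per bin). Directional variants restrict pairs to ±45° cones around
the north–south and east–west axes; with that tolerance the two cones
partition all pairs (ties on the diagonal, and zero-displacement pairs,
go to east–west).

Fitting minimises the plain average of squared deviations between the
binned surface and the model over `(sill, nugget, range, K)`, with
box constraints, by L-BFGS-B from 8 jittered starts (a pair-count
weighted objective exists but is off by default). One deliberate choice:
the objective evaluates the model at each bin's *count-weighted mean
pair lag*, not its geometric midpoint. Mobile campaigns sample on a lag
lattice (multiples of the sampling interval and the route clock
offsets), so pair lags sit near bin edges; midpoint evaluation biased
the fitted range upward by roughly a third in our recovery experiments,
while mean-lag evaluation is unbiased. `lag_summary = "center"`
restores the midpoint convention.

`fit_method_models()` builds the usual model line-up — ordinary kriging
from the variogram of the data, simple kriging and external-drift
kriging from the variogram of the station residuals $Z - F(t)$ — and by
default picks each surface's family by smallest objective. On synthetic
fields this reliably selects the generating family; misspecified
families on a cleanly exponential surface tend to degenerate into
temporal-only metrics (K at its bound), which is a model-selection
problem, not a prediction method. Passing an explicit `families` vector
pins the classic spherical/linear/exponential line-up instead.

**Predictors.** All three kriging systems are solved locally over the
`n_max = 50` metrically nearest neighbours (configurable; `Inf` is
global kriging). The neighbourhood size is a numerical economy: dense
solves at 50 points are trivial, and with a bounded variogram the
excluded far points carry near-zero weight.

* **SK on residuals** assumes the mean is *known* and equal to $F(t)$:
  residuals $r_i = Z_i - F(t_i)$ are kriged as a zero-mean field in
  covariance form, $C(d) = \mathrm{sill} + \mathrm{nugget} - \gamma(d)$,
  and the prediction is $F(t_0) + \sum_i \lambda_i r_i$. The covariance
  form is the well-posed simple-kriging system; a literal
  variogram-form solve is available behind a flag for comparison.
* **OK** assumes a constant unknown (locally estimated) mean:
  variogram-form system with $\sum_i \lambda_i = 1$ through a Lagrange
  multiplier $\mu$; variance $\sum_i \lambda_i \gamma_{i0} + \mu$.
* **KED** writes the mean as $a_0 + a_1 F(t)$ and solves the bordered
  system with both unbiasedness constraints
  $\sum_i w_i f_l(x_i,t_i) = f_l(x,t)$. A neighbourhood in which all
  $F(t_i)$ are equal makes the drift matrix rank-deficient; this raises
  a classed error rather than silently degrading, and the evaluation
  layer catches it and falls back to OK with a logged flag, so method
  comparisons cannot be silently contaminated.
* **IDW** is the deterministic baseline with the combined distance
  $d_i = \sqrt{\Delta x^2 + \Delta y^2 + C\,\Delta t^2}$, power
  $p = 2$; $C$ is tuned by seeded k-fold cross-validation over 10
  log-spaced candidates in $[10^{-4}, 10^4]$ (ties to the smaller $C$).

**Exactness and the nugget.** Data-to-data semivariances use
$\gamma(0) = 0$; target-to-data semivariances use the limit from above
(the nugget at zero lag). Consequently all three kriging predictors
reproduce data values exactly when the nugget is zero, and *filter*
rather than reproduce noisy data when it is positive — the nugget
represents micro-scale variation plus measurement error, and an
estimator that honoured noisy values exactly would be reproducing noise.
Kriging variances are analytically non-negative; values that come out
a hair negative through floating point are clamped at zero (with a
warning beyond 10⁻⁶). Singular systems get an escalating diagonal
jitter of $10^{-10} (\mathrm{sill+nugget}) \times 10^k$, $k \le 3$,
logged, before failing.

## Validation design

Three held-out designs mimic increasingly hard prediction problems on
the prediction day (the campaign's last day; all days feed variography,
which is fitted once and reused across folds — refitting per fold would
be expensive and barely change a fit dominated by the other days):

1. **random_points** — uniform random held-out points: interpolation
   between sampled places;
2. **path_segments** — contiguous single-sensor runs held out (lengths
   from a normal spec, default mean 20 samples): extrapolation *near*
   the sampled paths;
3. **leave_line_out** — entire routes held out: extrapolation far from
   all sampled trajectories.

Because training fractions vary per cell, "k-fold" means k independent
seeded re-draws per cell rather than disjoint quarters;
leave-line-out cycles deterministically over the held-out routes.
Indicators are RMSE, bias and Pearson correlation (undefined
correlations propagate as missing, never zero), and the report adds the
relative RMSE improvement of each kriging method over IDW. IDW's $C$ is
tuned once on the full day and frozen across folds so the baseline
cannot leak fold structure.

## The synthetic campaign

The generator emulates the structure of a tram-based ozone campaign:

* **Routes**: four crossing 4–5 km polylines spanning a ~5 km city
  core, traversed back and forth at 8 m/s, sampled every 40 s during a
  07:00–17:00 daily window for 2 days (the last day is the prediction
  day). Route sampling clocks are staggered (offsets 0/30/60/0 s):
  cross-route pairs at sub-interval lags are what identifies $K$, and
  the two shared-clock lines produce occasional simultaneous
  near-crossing samples whose near-zero metric distance anchors the
  nugget — without them those parameters are unidentifiable from
  lattice-sampled data.
* **Field**: $Z = \mu(t) + Y(x,t)$ with a raised-cosine diurnal mean
  (base 45 µg/m³, amplitude 25, peak 14:00, clipped at 0) and $Y$ a
  Gaussian field with exponential metric variogram, sill 60 (µg/m³)²,
  nugget 2, range 20 km, $K = 100$ m/s. These defaults reproduce the
  dimensionless regime of published tram-campaign fits rather than any
  particular numbers: temporal variability dominates spatial
  variability at city scale ($\gamma(0, 3\,\mathrm{h}) >
  \gamma(3\,\mathrm{km}, 0)$), the nugget is a few percent of the
  plateau, and consecutive same-vehicle samples stay substantially
  correlated ($K\,\Delta t / \mathrm{range} \approx 0.2$).
* **Sensors**: raw readings invert the calibration,
  $X = (Z - a^*)/b^*$, with biases $a^* \in [-4, 6]$ µg/m³,
  $b^* \approx 2$ (the ppb-to-µg/m³ scale), plus i.i.d. noise
  (sd 1 raw ≈ 2 µg/m³ calibrated).
* **Station**: the fixed station records the *same* field realisation —
  mobile samples and a 10-minute station sub-grid are one joint
  Gaussian draw — averaged into hourly nodes (the hour-wide window
  centred on each node).

Simulation is exact (dense Cholesky of the smooth covariance, nugget
added as i.i.d. micro-scale noise) up to a cap of 8000 points, chosen
so the default campaign (~7500 points) is simulated exactly; beyond the
cap, a seeded support subset is drawn exactly and the remaining points
get conditional-distribution draws (mean plus conditional-variance
noise) given their 32 nearest support points. The approximation keeps
marginal variances right but makes off-support pairs conditionally
independent given the support, so sub-support-scale correlation is
slightly distorted — recovery tests use campaigns under the cap.

What the generator does **not** emulate: street-canyon chemistry, wind-
or traffic-driven anisotropy, sensor drift over time,
humidity/temperature confounding, GPS error, and irregular tram
schedules. Passing tests therefore demonstrate that the pipeline is
internally correct and recovers known structure under its own
assumptions — not that those assumptions hold for any particular real
network.

## Numerical and design choices

* Degenerate inputs raise classed conditions
  (`stkrige_drift_degenerate`, `stkrige_extrapolation`,
  `stkrige_singular_system`, ...) so callers can react precisely;
  structured log messages (`stkrige_log`) carry stage/event/counts.
* Observations outside the station span are excluded (with a count)
  wherever $F(t)$ is needed — the station is a measured reference and
  is never extrapolated.
* Exact duplicate space-time points are deduplicated defensively before
  variography and, on singularity, inside OK.
* Default fitting bounds: sill, nugget in $[0, 10\,\mathrm{var}(z)]$;
  range in 10 m to 10× the maximum metric lag; $K \in [0.1, 10^4]$ m/s.
* Problem sizes in the shipped tests and the acceptance script (default
  campaign ~7.2k mobile samples, 2-day span, 20-bin temporal grids,
  5–10 seeds per study) were chosen as the package's desk-scale
  defaults; every size is a parameter, and the studies scale up
  unchanged.

## Known limitations

* The metric model forces identical spatial and temporal covariance
  shapes; product–sum or other separable/non-separable families are out
  of scope, as are cokriging, universal kriging and block kriging.
* Local kriging with a fixed `n_max` can produce small discontinuities
  where the neighbour set changes.
* The calibration scheme's attenuation (above) means absolute levels of
  calibrated mobile data inherit the station's temporal mean; method
  comparisons are unaffected, absolute exposure estimates should be
  read with this in mind.
* Kriging predictions cannot leave the convex hull of training values;
  extrapolation far from all routes reverts toward the (station or
  local) mean with saturating variance — informative uncertainty, but
  no new information.
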