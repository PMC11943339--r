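---
title: "Projecting insect voltinism from gridded climate ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting insect voltinism from gridded climate ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltigrid)
```

## The scientific question and the model

Multivoltine ectotherms complete more generations per year when the
thermal budget of the growing season increases. For insects whose
development is approximately linear in temperature between a lower
developmental zero and the damaging extremes, the growing degree-day
model summarises that budget in one number per year: the cumulative
growing degree days

$$\mathrm{CGDD} = \sum_{i} \max(T_i - T_0,\, 0),$$

the annual sum over daily mean temperatures $T_i$ of their exceedance
over the developmental zero $T_0$. Voltinism is then the continuous
ratio

$$N = \mathrm{CGDD} / K,$$

where $K$ (degree-days) is the effective temperature accumulation
needed for one complete generation. $N$ is deliberately **not** floored:
a change from 1.4 to 1.9 "generations" is ecologically meaningful (a
longer second-generation window) even though no complete second
generation fits yet.

Two assumptions are built in and inherited by everything downstream:

* **Linearity, no upper threshold.** Development accrues
  proportionally to temperature above $T_0$ with no high-temperature
  cutoff and no diapause switch. This is intentional fidelity to the
  degree-day formulation; it overestimates development during extreme
  heat and ignores photoperiod-induced diapause.
* **Daily means suffice.** Sub-daily fluctuation around the mean is
  ignored; near $T_0$ this biases CGDD slightly low (warm afternoons of
  cold days do not count).

The whole-generation parameters shipped with the package are
$T_0 = 9.95 \pm 0.61$ °C and $K = 1698.18 \pm 48.18$ degree-days for the
pine caterpillar, with stage-wise rows (larvae after overwintering,
pupae, egg, larvae before overwintering) whose $K$ values sum to the
whole-generation value up to rounding of the printed numbers
(`stage_table_consistency()` checks the 0.02 degree-day slack). The
quoted uncertainties are propagated — not formally, but as a bracketing
band — by `parameter_uncertainty_band()`, which recomputes $N$ with
$(T_0 + \mathrm{SE},\, K + \mathrm{SE})$ and
$(T_0 - \mathrm{SE},\, K - \mathrm{SE})$; the shifted $T_0$ enters the
CGDD sum itself, since the threshold interacts nonlinearly with the
seasonal cycle.

A useful closed form anchors intuition and several tests: if **every**
day of a 365-day year sits above $T_0$, a uniform warming of
$\Delta T$ adds exactly $365\,\Delta T$ degree-days and
$365\,\Delta T/K \approx 0.215\,\Delta T$ generations. Real (and
synthetic) seasonal series have sub-threshold winters, so realized
sensitivities must fall strictly below that ceiling; how far below
depends on how many days the warming lifts across the threshold.

## The synthetic climate generator

The analysis was designed for two gridded inputs — an observed baseline
of daily mean temperature and an ensemble of downscaled GCM scenario
members — that are too large to ship and require external archives. The
generator therefore produces both with the statistical structure the
method actually exploits, so every stage runs and is testable offline.
Its defaults describe a warm-temperate coastal province spanning
34.5–38.5 °N × 114.5–122.75 °E on a 0.25° grid, with spatial annual
means in the 11–14 °C range.

Daily temperature at a cell is

$$T = \bar T_{\mathrm{cell}} + w(y) + u_y + A\,s(d) + \epsilon_d,$$

with, and with these defaults and reasons:

* $\bar T_{\mathrm{cell}}$: reference annual mean **14.2 °C** at the
  domain-centre latitude at sea level, meridional gradient
  **−0.8 °C per °lat** northward, lapse rate **−6.5 °C/km** (the
  standard-atmosphere value) applied to a synthetic DEM. Together these
  put the domain mean near 12.3 °C, inside the observed 11.2–14.4 °C
  band of the emulated region.
* $s(d)$: a single sinusoid with its minimum on day-of-year 15 and
  amplitude **A = 14 °C** — the simplest shape that yields realistic
  below-/above-threshold day splits (sub-zero midwinters, mid-20s
  midsummers) for a temperate site.
* $\epsilon_d$: AR(1) daily noise, stationary SD **2 °C**, lag-1
  autocorrelation **0.7**, initialised from the stationary
  distribution and continuous across year boundaries; one realisation
  is shared across the domain (synoptic weather is large-scale at this
  extent). $u_y$: interannual year effects, SD **0.3 °C**, also shared.
* $w(y)$: the warming path — a baseline trend of **+0.3 °C/decade**
  centred on the baseline-period midpoint, and under a scenario a ramp
  from 2015 whose slope is solved (the anomaly is affine in the slope,
  so two evaluations give the exact solution) so that the 2081–2100
  mean of the path minus its 1979–2018 mean equals the scenario's
  configured end-of-century warming *exactly*. The four default
  scenarios use **+2.37, +3.45, +4.35, +5.49 °C** for SSP1-2.6 through
  SSP5-8.5. Warming is spatially uniform by default; an optional
  mean-preserving west-amplified pattern is available.
* Pseudo-GCM members perturb this "observed" field with an additive
  bias, a seasonal-amplitude inflation factor, extra white noise, and
  their own noise seed. The default ensemble has **5 members** (enough
  to exercise ranking and selection at desk scale) spanning biases of
  ±1.2 °C, inflations 0.85–1.15, and noise SDs 0.2–1.5 °C, with one
  near-faithful member so "selection finds the good model" is a real
  property.

The DEM is three Gaussian hills (a central massif above 1000 m, lower
eastern hills, southern foothills) over a low western plain plus seeded
roughness; at the default domain it populates all three elevation
analysis bands. A `relief_amplitude` of 0 collapses it to the flat base
elevation.

**What the generator does not emulate** — and hence what passing tests
do and do not show about real data: no precipitation/humidity coupling,
no heat waves or cold spells beyond what AR(1) noise produces, no
spatially correlated weather *anomalies* (the shared-noise choice makes
cells perfectly correlated instead), no realistic GCM error structure
(real model biases are seasonally and regionally patterned, not a
constant offset), and no real geography. Tests on synthetic data
demonstrate that the *computational pipeline* is correct and that the
method recovers *configured* signals; they do not validate the
degree-day model against field observations.

## Ensemble evaluation and averaging

Members are compared against the baseline on the **domain-mean daily
temperature series** over the overlapping historical years — the
natural series when the target quantity is a domain-scale thermal
budget. `taylor_statistics()` reports Pearson $r$, both standard
deviations, the normalized SD $\hat\sigma$, the centered RMSE, and the
mean bias; SD and cRMSE use the $1/n$ convention so the Taylor identity
$\mathrm{cRMSE}^2 = \sigma_s^2 + \sigma_o^2 - 2\sigma_s\sigma_o r$
holds exactly (tested at 1e-9). Both raw and obs-normalized cRMSE are
emitted, since published single-number summaries are often on the
normalized scale.

No standard rule exists for turning a Taylor triple into a ranking, so
the package adopts the widely used skill score

$$S = \frac{(1+r)^4}{4\,(\hat\sigma + 1/\hat\sigma)^2} \in (0, 1],$$

which is 1 exactly when $r = 1$ and $\hat\sigma = 1$, and penalises
both decorrelation and variance mismatch. `rank_and_select()` sorts by
$S$ (ties alphabetically, for determinism) and keeps the top $k$
(default 3). Equal weighting is the default for the ensemble mean;
skill-proportional weights are available. Note that $S$ is insensitive
to constant bias — a deliberately forgiving choice matching the use of
centered statistics for pattern evaluation.

## Grids, calendars, and regridding

All internal temperatures are °C; coordinates are cell centres in
degrees, stored ascending. The default calendar is **365-day no-leap**
for all synthetic data, which matches common climate-model output and
makes analytic expectations exact (every year contributes exactly 365
days to CGDD); proleptic-Gregorian grids are supported, and Feb 29 is
then simply included in the annual sum. NetCDF I/O is CF-style
(`lon`/`lat`/`time`, `tas` in °C with Kelvin auto-converted on read,
elevation as a static variable).

Interpolation onto the common analysis grid is **bilinear**: exact on
fields linear in latitude/longitude, never outside the source min/max
envelope, idempotent on its own lattice (both properties are tested),
and with no extrapolation — target centres outside the source
cell-centre hull are masked. Conservative area-weighted remapping is
out of scope; for smooth temperature fields at these resolutions the
difference is far below the noise level of the analysis. Elevation is
regridded the same way. Point extraction uses the nearest cell centre
by great-circle distance with ties broken to the south-west cell.

## Gradients, trends, and regressions

Cells are stratified by elevation — $[0, 500)$, $[500, 1000]$,
$(1000, \infty)$ m, so both boundary values land in the middle band —
and by left-open/right-closed latitude intervals. Bin summaries are
**unweighted cell means**: over a 4° latitude band the cos-latitude
area distortion is below half a percent, far less than other error
sources, and unweighted means keep every oracle exact.

Decadal trends are OLS of annual values on calendar year with the slope
scaled ×10 and a t-based 95% CI computed directly from the slope
standard error (avoiding `summary.lm`'s degenerate-fit warnings). Two
conventions for degenerate inputs: a constant series returns slope 0
and $R^2 = 0$ (the 0/0 case is defined as "no variance explained"), and
a perfect fit returns a zero-width CI. Warming sensitivity is OLS of
pooled annual anomalies $\Delta N$ on $\Delta T$ (both relative to the
baseline-period mean), per bin and scenario, with predicted $\Delta N$
at +1.0, +1.5 and +2.0 °C reported; pooling one point per projection
year per scenario mirrors how such fits are usually displayed.

## The pipeline and determinism

`run_pipeline()` executes synth → evaluate/select → per-scenario
ensemble → regrid → CGDD/voltinism → gradients, writes every
intermediate artifact (NetCDF/CSV), and emits a JSON manifest with all
applied parameters, the seed, and MD5 checksums. The seed is mandatory
in every config — there is no silent default — and all random draws
derive from it, so identical configs give byte-identical artifacts
(NetCDF output carries no timestamps); the test suite asserts checksum
equality across reruns. Stage failures abort with the stage name.

The packaged test profile runs the pipeline at 0.5° over an 8-year
baseline with 2–3 members, two scenarios, and a subsampled projection
period; unit and property tests use 1-cell to 2×4-cell grids and 5–40
year series, with 20-seed replications where a property holds only in
expectation. These sizes were chosen so that the complete suite
exercises every stage, including two full pipeline runs, in about a
minute on one core.

## Known limitations

* The degree-day model's linearity and missing upper threshold /
  diapause are the dominant scientific caveats; both are inherited by
  design.
* The ± band from `parameter_uncertainty_band()` is a bracketing
  interval, not a confidence interval: it assumes the $T_0$ and $K$
  errors are perfectly anticorrelated in their effect on $N$.
* The synthetic generator's spatially shared noise means ensemble
  statistics computed on *per-cell* series (rather than the
  domain-mean series used here) would be unrealistically favourable.
* Taylor evaluation on the domain-mean series rewards large-scale
  fidelity only; a member could be skilful here yet poor at the cell
  scale.
* Bin means are unweighted; a `cos`-latitude weighting switch would be
  needed for domains spanning many more degrees of latitude.
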