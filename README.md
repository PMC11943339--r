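# voltigrid

Degree-day voltinism projections on gridded climate ensembles.

`voltigrid` asks how much climate warming increases the number of
generations per year (**voltinism**) of a temperature-driven insect, and
where — across elevation bands and latitude bands — that increase is
largest. It is parameterised for the pine caterpillar (*Dendrolimus
spectabilis* Butler), a defoliator of temperate conifer forests whose
development is well described by a linear degree-day model, but every
parameter is replaceable, so any multivoltine ectotherm with known thermal
constants can be analysed.

The package is aimed at forest-entomology and climate-impact researchers
who want the full pipeline — climate ensemble in, gradient-resolved
voltinism projections out — as tested, scriptable R functions rather than a
one-off GIS workflow.

## The model

For daily mean air temperature `T_i` (°C) in a calendar year, the annual
cumulative growing degree days above the developmental zero `T0` are

    CGDD = Σ_i max(T_i − T0, 0)        [degree-days]

and voltinism is the continuous ratio

    N = CGDD / K                        [generations · yr⁻¹]

where `K` is the effective temperature accumulation required for one
complete generation (egg → adult). The packaged constants, from rearing
experiments under natural variable temperature, are `T0 = 9.95 ± 0.61` °C
and `K = 1698.18 ± 48.18` degree-days, with stage-wise values for larvae
after overwintering, pupae, eggs, and larvae before overwintering.
Projected change is reported as `ΔN = N_future − N_baseline` per grid
cell, stratified into elevation bands (<500, 500–1000, >1000 m) and
latitude bands ((34.5–35], …, (38–38.5] °N), with decadal trends and the
sensitivity `dN/dT` (generations per °C of annual-mean warming) from OLS
regression of pooled annual anomalies.

Around that core the package provides:

* a seeded **synthetic climate generator** (baseline grid + pseudo-GCM
  scenario members with distinct bias/variance/noise) so the whole
  pipeline runs and is testable without downloading climate archives;
* **Taylor-statistic evaluation** (r, SD ratio, centered RMSE) with a
  skill score `S = (1+r)⁴ / (4(σ̂ + 1/σ̂)²)`, member selection, and equal-
  or skill-weighted **ensemble means**;
* **bilinear regridding** onto a common analysis grid, NetCDF I/O (CF
  style, `tas` in °C), and a YAML-configured, manifest-writing
  **pipeline runner**.

## Worked example

```r
library(voltigrid)

params <- dev_params()
compute_cgdd(c(8, 10, 12, 14), params$t0)
#> [1] 6.15                       # only exceedances over 9.95 °C accrue
compute_voltinism(c(2132.93, 2651.25), params)
#> [1] 1.256009 1.561230          # generations per year, not floored

# end-to-end run at a coarse desk-scale profile
cfg <- synth_config(resolution = 0.5, years = 1979:1986,
                    baseline_years = 1979:1986, seed = 11)
rc <- run_config(cfg,
                 scenarios = default_scenarios()[c("SSP1-2.6", "SSP5-8.5")],
                 members = default_members()[1:3],
                 analysis_resolution = 0.25,
                 windows = list("2090s" = 2093:2100),
                 projection_years = seq(2019, 2100, by = 12),
                 select = 2, out_dir = file.path(tempdir(), "demo"))
man <- run_pipeline(rc, quiet = TRUE)
print(report_summary(man), digits = 3)
#>    scope scenario  period mean_voltinism sd_voltinism mean_cgdd delta_voltinism
#> 1 domain baseline current           1.23       0.0668      2088              NA
#> 2 domain SSP1-2.6   2090s           1.46       0.0288      2475           0.228
#> 3 domain SSP5-8.5   2090s           1.93       0.0420      3270           0.696
#>   delta_t trend_per_decade
#> 1      NA           0.0920
#> 2    1.88           0.0249
#> 3    5.24           0.0825
```

Reading the table: over this synthetic baseline the domain averages 1.23
generations per year. By the 2090s the low-forcing scenario adds 0.23
generations for 1.9 °C of warming, the high-forcing scenario 0.70
generations for 5.2 °C — voltinism rises monotonically with radiative
forcing, and the implied sensitivity stays below the analytic ceiling
`365/K ≈ 0.215` generations per °C because winter days sit below the
developmental zero. The run directory additionally holds `taylor.csv`
(member evaluation), `bins.csv`, `trends.csv`, `regressions.csv`
(per-band `dN/dT` fits with predictions at +1, +1.5, +2 °C), NetCDF
fields, and a `manifest.json` with seeds and artifact checksums; reruns
with the same config are checksum-identical.

A thin command-line wrapper for shell use ships at
`inst/cli/voltigrid.R` (subcommands `run-all`, `synth`, `evaluate`,
`regrid`, `voltinism`, `report`).

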