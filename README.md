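# bcvcalc

Multi-scheme calculation and comparison of the 19 standard bioclimatic
variables (BCVs, BIO1–BIO19) from gridded temperature and precipitation
time series.

## Why

BIO1–BIO19 are the most widely used predictors in species distribution
modeling, yet they have no single canonical recipe. Implementations
differ silently in at least four ways:

* **Period-of-interest (POI) selection.** The wettest/driest/warmest/
  coldest month or quarter can be identified once from the whole-period
  monthly climatology and then averaged as a fixed calendar period
  (**CLIM**), or identified separately within each year and the per-year
  values averaged (**BIO**). On any climate with interannual variability
  the two disagree — most strongly where the POI is defined by
  precipitation.
* **Monthly temperature extremes** (BIO5/BIO6). A month can be
  summarized by its *mean* of daily maxima/minima, or by its single most
  extreme (*absolute*) daily value. In maritime climates with flat
  diurnal cycles the two can differ by more than 15 °C, and the two
  statistics need not even peak in the same calendar month.
* **Mean temperature source.** `tmean` taken directly from the dataset,
  or reconstructed as `(tmin + tmax) / 2` as climatology databases that
  only ship extreme temperatures must do.
* **Quarter convention.** A quarter is three consecutive months labeled
  by its median month; the quarter centered on January of year *y* is
  December *y−1* – February *y*. Some implementations instead wrap
  within the calendar year (November–December–January of the *same*
  year), which is defensible for climatologies but wrong for time
  series.

`bcvcalc` makes every one of these switches an explicit field of a
`scheme_config()`, attaches the full recipe to every result, and ships
the diagnostics needed to quantify what a switch does to a dataset:
circular month-shift statistics, scheme-agreement fractions, and Taylor
statistics (normalized SD `σ̂ = σ_f/σ_r`, centered RMSE, Pearson *r*,
linked by `RMSE² = σ̂² + 1 − 2σ̂r`).

The standard formulas are used throughout, e.g. BIO4 = 100 × SD of the
12 climatological monthly mean temperatures, BIO3 = 100 × BIO2 / BIO7,
BIO15 = 100 × SD / (mean + 1) of climatological monthly precipitation.

A seeded synthetic-climate generator (sinusoidal seasonal cycles,
unimodal/bimodal circular precipitation regimes with integer peak-month
jitter, spatial regime mosaics, daily disaggregation with optional heat
spikes) provides controlled inputs for which every scheme divergence is
known by construction.

## Worked example

```r
library(bcvcalc)

# a Mediterranean winter-rain regime next to a continental summer-rain
# regime, 30 years of monthly data
med  <- synthetic_climate_spec(peak_months = 12, peak_sharpness = 2,
                               temp_amplitude = 6, seed = 1)
cont <- synthetic_climate_spec(peak_months = 7, temp_amplitude = 13,
                               precip_scale = 480, seed = 2)
series <- generate_regime_mosaic(list(med, cont))
series
#> <climate_grid> monthly, 5 x 6 boxes, 360 steps (1991-01-01 to 2020-12-01)
#>   variables: tmin, tmax, tmean, precip

clim <- compute_all_bcvs(series, scheme_config(poi_scheme = "CLIM"))
bio  <- compute_all_bcvs(series, scheme_config(poi_scheme = "BIO"))
clim
#> <bcv_result> 19 variables, 5 x 6 boxes, period 1991-2020
#>   scheme: CLIM / mean extremes / tmean direct / consecutive_median quarters

round(clim$values$bio8[1:3, 1:3], 1)   # wettest-quarter temperature, degC
#>      [,1] [,2] [,3]
#> [1,] 10.1  9.6  9.1
#> [2,]  8.9  8.4  8.0
#> [3,]  7.8  7.3  6.7

# do the two schemes even pick the same wettest quarter?
poi_agreement_fraction(clim$poi$wettest_quarter, bio$poi$wettest_quarter)
#> [1] 0.6666667

# how far does the wettest quarter wander from year to year?
shift <- interannual_poi_shift(bio$poi$wettest_quarter, reference = "modal")
shift$max_shift                        # months, domain maximum
#> [1] 1.142857

head(bcv_suite_comparison(bio, clim), 4)
#>   variable normalized_sd centered_rmse correlation  n flag
#> 1     bio1     1.0000000    0.00000000   1.0000000 30
#> 2     bio2     1.0000000    0.00000000   1.0000000 30
#> 3     bio3     0.9776499    0.02475444   0.9999421 30
#> 4     bio4     1.0000000    0.00000000   1.0000000 30
```

The agreement fraction of 0.67 and the (1, 0, 1) Taylor rows for purely
temperature-based variables reproduce, on synthetic data, the hallmark
pattern of real Mediterranean-domain comparisons: scheme choice barely
matters for temperature-defined BCVs and matters a lot wherever
precipitation defines the period of interest.

Grids are exchanged as CF NetCDF (`read_cf_grid()` / `write_cf_grid()`,
with automatic K→°C and m→mm conversion at ingest) and BCV stacks as
per-variable ESRI ASCII grids or NetCDF (`write_bcv()` /
`read_bcv_stack()`). A thin CLI wraps the same functions:

```sh
inst/cli/bcvtool synth   --spec spec.yaml --out synthetic.nc
inst/cli/bcvtool compute --config run.yaml
inst/cli/bcvtool compare --a stackA/ --b stackB/ --out taylor.csv
inst/cli/bcvtool shifts  --input monthly.nc --out diag
```

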