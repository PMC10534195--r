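---
title: "Calculation schemes for bioclimatic variables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calculation schemes for bioclimatic variables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcvcalc)
```

## The problem

The 19 standard bioclimatic variables condense monthly temperature and
precipitation into annual summaries (annual mean temperature,
temperature of the warmest quarter, precipitation of the driest month,
…) that species distribution models consume as predictors. The
definitions sound unambiguous but are not: whenever a variable refers to
"the wettest quarter" or "the maximum temperature of the warmest
month", an implementation has to decide *how that period is found* and
*how its value is summarized*. Different choices produce systematically
different predictor fields, and models trained on one convention are not
comparable with models trained on another. bcvcalc exists to make those
choices explicit, computable under every variant, and measurable against
each other.

## The scheme space

`scheme_config()` spans four independent axes.

**CLIM vs BIO period-of-interest selection.** Let $x_{m,y}$ be the
monthly value of the selecting variable (precipitation for wettest/
driest, mean temperature for warmest/coldest quarters, etc.) in calendar
month $m$ of year $y$, and $\bar x_m = \frac1Y\sum_y x_{m,y}$ the
climatology. The CLIM scheme selects once,
$m^\ast = \arg\max_m \bar x_m$, and reports the climatological value at
$m^\ast$; it is temporally consistent (always the same calendar period)
but in an individual year $m^\ast$ need not actually be the wettest
month. The BIO scheme selects within each year,
$m^\ast_y = \arg\max_m x_{m,y}$, and reports
$\frac1Y\sum_y x_{m^\ast_y,y}$; it always honors the *definition* of the
variable but the selected period wanders between years, so the variable
can mix different seasons. For month-extreme variables the schemes are
ordered (a maximum of per-year maxima can only exceed the mean of a
fixed month: BIO ≥ CLIM for BIO13, BIO ≤ CLIM for BIO14); for quarter
variables the relationship is not monotone and is precisely what the
diagnostics quantify. On any input whose annual cycle repeats
identically every year the two schemes coincide — a limit the test
suite checks exactly.

**Mean vs absolute extremes (BIO5/BIO6).** A month's maximum
temperature can be the monthly mean of daily maxima or the single
highest daily value. The two statistics differ most where the diurnal
cycle is flat and single advective extremes stand out, and they need not
peak in the same calendar month. Under the absolute scheme the selection
series *is* the absolute series: CLIM pools the absolute extreme across
all years' instances of each calendar month and picks the month holding
the period-wide extreme; BIO takes each year's most extreme month and
averages. The absolute scheme requires daily-resolved input:
`aggregate_daily_to_monthly()` carries the per-month absolute daily
extremes (`tmax_abs`, `tmin_abs`) alongside the monthly means, and
requesting absolute extremes from monthly-only data is an error rather
than a silent fallback.

**Mean temperature source.** `direct` uses the dataset's own mean
temperature; `from_minmax` computes $(T_{min}+T_{max})/2$ at the
series' native resolution before any averaging. On daily data with
skewed diurnal distributions the two differ visibly (the package's
tests construct such cases); the difference shrinks as resolution
coarsens.

**Quarter convention.** Quarters are three consecutive months labeled
by the median month. Under `consecutive_median` the January-centered
quarter of year $y$ uses December of $y-1$; under `same_year_wrap`
all members come from year $y$ (the convention of climatology-oriented
code). The two agree on every window that does not cross the year
boundary — a property test in the suite.

## Numerical and boundary choices

* **Formula switches.** BIO4 uses $100\times$ the sample SD (n−1) of
  the 12 climatological monthly means; BIO15 uses
  $100 \times \mathrm{SD}/(\overline{P}+1)$. Both are config switches
  (`bio4_sd`, `bio15_offset`) because published implementations differ;
  the defaults follow the convention of the WorldClim-companion code so
  that comparisons against distributed reference layers are meaningful.
  The +1 mm offset also keeps all-dry cells at 0 instead of 0/0.
* **CLIM quarters are evaluated on the climatology, circularly.** The
  12 candidate quarters are built from the 12 climatological slots with
  Dec–Jan wrap-around, so CLIM has no edge-year problem. BIO quarters
  under `consecutive_median` need December of the year before the
  period and January of the year after; the `edge_policy` controls what
  happens when they are absent: `extend` demands the extra months,
  `drop-edge-year` (default) drops affected years from the per-year
  averaging, `strict-missing` marks affected quarters missing. The
  default was chosen because a one-year extension is simply not
  available at the boundaries of real dataset coverage.
* **Tie-breaking** is always the earliest calendar month —
  deterministic and independent of evaluation order. **Degenerate**
  grid boxes (zero-variance selection series, e.g. zero precipitation
  all year) select month 1 and carry a `degenerate` flag rather than
  going missing, so desert cells still produce a complete BCV vector.
* **Missing data.** Daily aggregation follows the 80% completeness
  convention of station-based gridded datasets: a month with fewer
  non-missing days than `completeness_threshold` × days-in-month is
  missing (the threshold is the explicit rule; within an accepted month
  the available days are averaged). Climatological slots average the
  contributing years and are missing only when no year contributes; a
  missing member month makes its quarter missing; no gap-filling is
  ever performed, so sparse-observation artifacts surface instead of
  being imputed. In `compute_all_bcvs()` a variable whose requirements
  are not met becomes a missing layer, never a global abort.
* **Calendar.** Gregorian with leap days; month lengths are true
  days-in-month. 360-day and no-leap model calendars are out of scope
  and rejected at ingest.
* **Shift statistics.** Month distances are circular,
  $d(a,b)=\min(|a-b|,\,12-|a-b|)\in[0,6]$. The signed timing shift
  between absolute and mean maxima reports "absolute later" as
  positive and maps the ambiguous antipodal case to +6. The mean
  interannual POI shift is, by default, the mean circular distance of
  each year's choice from the *modal* per-year choice, with
  `climatological` and `consecutive` (year-to-year) references
  available as options — the literature's phrase "mean interannual
  shift" does not pin down the baseline, so all three are computable
  and none is asserted as canonical.
* **Taylor statistics** use pairwise-complete masked boxes, sample SDs,
  and normalize both the field SD and the centered RMSE by the
  reference SD, so each suite row satisfies
  $\mathrm{cRMSE}^2=\hat\sigma^2+1-2\hat\sigma r$ to numerical
  precision (asserted at $10^{-10}$ in the tests). Domain summaries of
  difference maps report both the raw mean and a 1.5×IQR-trimmed mean;
  no area weighting is applied by default.

## The synthetic generator

`synthetic_climate_spec()` emulates exactly the features that make the
scheme axes diverge, and nothing more:

* sinusoidal annual temperature cycles with configurable amplitude
  (continentality) and a linear trend (default 0.3 °C/decade, a
  realistic late-20th-century mid-latitude value);
* a circular (von-Mises-like) seasonal precipitation shape — chosen
  over a truncated Gaussian precisely so December–January-spanning
  rainy seasons are first-class citizens of the quarter logic — with
  one or two peak months whose position jitters from year to year by a
  rounded Gaussian draw (default SD 1 month, the order of interannual
  variability seen in Mediterranean-type regimes);
* the jitter is an *integer* month shift drawn once per year per
  regime, so the true wettest month and quarter of every year are known
  by construction and the POI machinery can be tested against an exact
  oracle, and the regime shifts coherently across its grid boxes as
  synoptically driven variability does;
* spatial structure only through deterministic gradients (temperature
  with latitude, continentality and precipitation scale with longitude)
  and through block mosaics of adjacent regimes;
* daily disaggregation that spreads monthly values uniformly with
  optional daily noise, plus an optional heat spike that adds a fixed
  excursion to one day's maximum at a known month offset from the
  seasonal peak — giving a constructed absolute-vs-mean gap and timing
  shift.

What the generator deliberately does **not** emulate: orography, spatial
autocorrelation beyond the mosaic blocks, realistic daily weather
(autocorrelated wet/dry spells, skewed daily precipitation), or any real
region's climate. Passing tests therefore demonstrate that the
*computational machinery* is correct under controlled conditions with
known truth; they do not validate any claim about a particular
real-world dataset, which always requires running the package on that
dataset.

Defaults describe a plausible western-Mediterranean monthly regime
(annual mean 12 °C, amplitude 8 °C, diurnal range 9 °C, 600 mm/yr
peaking in December, 30 years) and were fixed once, on domain grounds.

## Verification strategy and problem sizes

Three independent oracles back the test suite. (1) A straight-line
brute-force reimplementation of every selection and every BCV formula
(plain per-gridbox loops, no shared code) must agree elementwise with
the vectorized engine on random 5×5×10-year grids under both schemes.
(2) Constructions with known truth: injected heat spikes recover their
offset and magnitude; a sinusoid with a forced one-month shift matches
the closed form $A(\cos(\pi/6)-1)$; 200 years of integer peak jitter
match the analytic expected circular distance of the rounded Gaussian
within three Monte-Carlo standard errors. (3) Exact limits and
inequalities: periodic input collapses CLIM = BIO with agreement 1.0
and 19 Taylor rows of (1, 0, 1); absolute/mean and BIO/CLIM order
statistics hold on 100 random grids; BIO7 = BIO5 − BIO6 identically.
Test problem sizes (tens of boxes, 5–30 years, 200 years only for the
jitter statistics) were chosen as the smallest grids on which every
code path — year boundaries, mosaic boundaries, both schemes — is
exercised; the whole suite runs in well under a minute.

The NetCDF path was additionally validated in development against an
independent third-party NetCDF-3 implementation in both directions
(files written here parse there with identical values and vice versa);
the shipped tests assert bit-identical round trips.

## Known limitations

* NetCDF support covers the classic (CDF-1) format with standard
  Gregorian calendars — sufficient for the gridded-observation use
  case, not for NetCDF-4/HDF5 archives, which must be converted first
  (`nccopy -k classic`).
* BCV raster stacks use per-variable ESRI ASCII grids (plus a JSON
  provenance sidecar) as the text-based GIS interchange format; ASCII
  grids require square cells, so anisotropic grids must use the NetCDF
  stack format.
* Inputs must already share a grid; only cropping/subsetting is
  provided, never regridding or interpolation.
* No sub-daily aggregation, no non-standard model calendars, no extended
  (>19) variable sets, and no species-distribution modeling — the
  package ends where predictor generation ends.
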