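# Small in-code fixtures: hand-built monthly/daily grids.

mk_time_monthly <- function(years) {
  as.Date(sprintf("%04d-%02d-01", rep(years, each = 12L),
                  rep(1:12, length(years))))
}

# builds a monthly grid from per-variable vectors of length 12*nyears
# (recycled over space) or full [time, lat, lon] arrays
mk_monthly_grid <- function(years = 2001:2005, nlat = 1, nlon = 1,
                            tmean = NULL, tmin = NULL, tmax = NULL,
                            precip = NULL, tmax_abs = NULL,
                            tmin_abs = NULL) {
  nt <- 12L * length(years)
  shape <- function(v) {
    if (is.null(v)) return(NULL)
    if (is.array(v) && length(dim(v)) == 3L) return(v)
    array(rep(v, nlat * nlon), dim = c(nt, nlat, nlon))
  }
  climate_grid(lon = seq(0, by = 1, length.out = nlon),
               lat = seq(40, by = 1, length.out = nlat),
               time = mk_time_monthly(years),
               tmean = shape(tmean), tmin = shape(tmin),
               tmax = shape(tmax), precip = shape(precip),
               tmax_abs = shape(tmax_abs), tmin_abs = shape(tmin_abs))
}

mk_daily_grid <- function(years = 2001:2002, nlat = 1, nlon = 1,
                          tmean = NULL, tmin = NULL, tmax = NULL,
                          precip = NULL) {
  time <- seq(as.Date(sprintf("%04d-01-01", years[1])),
              as.Date(sprintf("%04d-12-31", years[length(years)])),
              by = "day")
  nt <- length(time)
  shape <- function(v) {
    if (is.null(v)) return(NULL)
    if (is.array(v) && length(dim(v)) == 3L) return(v)
    array(rep(v, length.out = nt * nlat * nlon), dim = c(nt, nlat, nlon))
  }
  climate_grid(lon = seq(0, by = 1, length.out = nlon),
               lat = seq(40, by = 1, length.out = nlat),
               time = time,
               tmean = shape(tmean), tmin = shape(tmin),
               tmax = shape(tmax), precip = shape(precip))
}

# random but physically consistent monthly grid (tmin <= tmean <= tmax,
# precip >= 0), independent values per month: a stress case for POI logic
random_monthly_grid <- function(nlat = 5, nlon = 5, years = 2001:2010,
                                seed = 1) {
  set.seed(seed)
  nt <- 12L * length(years)
  n <- nt * nlat * nlon
  tmean <- array(rnorm(n, 10, 6), dim = c(nt, nlat, nlon))
  half <- array(abs(rnorm(n, 4, 2)), dim = c(nt, nlat, nlon))
  precip <- array(pmax(0, rnorm(n, 50, 40)), dim = c(nt, nlat, nlon))
  climate_grid(lon = seq(0, by = 0.5, length.out = nlon),
               lat = seq(40, by = 0.5, length.out = nlat),
               time = mk_time_monthly(years),
               tmean = tmean, tmin = tmean - half, tmax = tmean + half,
               precip = precip)
}

# periodic multi-year grid: every year identical (CLIM and BIO must agree),
# spatially varying so field statistics are non-degenerate
periodic_grid <- function(nlat = 4, nlon = 4, years = 2001:2010, seed = 7) {
  set.seed(seed)
  one_year_t <- array(rnorm(12 * nlat * nlon, 10, 6),
                      dim = c(12, nlat, nlon))
  one_year_h <- array(abs(rnorm(12 * nlat * nlon, 4, 1)),
                      dim = c(12, nlat, nlon))
  one_year_p <- array(pmax(0, rnorm(12 * nlat * nlon, 60, 35)),
                      dim = c(12, nlat, nlon))
  rep_years <- function(a) {
    out <- array(0, dim = c(12 * length(years), nlat, nlon))
    for (y in seq_along(years)) {
      out[(y - 1) * 12 + 1:12, , ] <- a
    }
    out
  }
  climate_grid(lon = seq(0, by = 1, length.out = nlon),
               lat = seq(40, by = 1, length.out = nlat),
               time = mk_time_monthly(years),
               tmean = rep_years(one_year_t),
               tmin = rep_years(one_year_t - one_year_h),
               tmax = rep_years(one_year_t + one_year_h),
               precip = rep_years(one_year_p))
}
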