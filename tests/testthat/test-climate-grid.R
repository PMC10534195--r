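test_that("grid construction enforces the physical invariants", {
  expect_error(mk_monthly_grid(tmean = NULL), "at least one")
  t <- rep(5, 24)
  expect_error(
    mk_monthly_grid(years = 2001:2002, tmin = t + 1, tmax = t),
    "tmin > tmax")
  expect_error(
    mk_monthly_grid(years = 2001:2002, precip = c(-1, rep(1, 23))),
    "negative precipitation")
  # duplicate / non-uniform time axes are rejected
  tm <- mk_time_monthly(2001:2002)
  expect_error(
    climate_grid(lon = 0, lat = 40, time = c(tm, tm[1]),
                 tmean = array(1, dim = c(25, 1, 1))),
    "increasing|duplicate")
  expect_error(
    climate_grid(lon = 0, lat = 40, time = tm[-3],
                 tmean = array(1, dim = c(23, 1, 1))),
    "neither uniformly daily nor")
})

test_that("daily aggregation averages temperature, sums precipitation and
           extracts absolute extremes", {
  g <- mk_daily_grid(years = 2001, tmean = 5, precip = 2)
  m <- aggregate_daily_to_monthly(g)
  expect_equal(m$step, "monthly")
  expect_equal(m$tmean[1, 1, 1], 5)             # constant January mean
  expect_equal(m$precip[1, 1, 1], 62)           # 31 days x 2 mm
  expect_equal(m$precip[2, 1, 1], 56)           # 28 days x 2 mm
  # absolute extremes ride along
  tmax <- rep(20, 365)
  tmax[200] <- 41                               # one hot day in July
  g2 <- mk_daily_grid(years = 2001, tmax = tmax, tmin = tmax - 10)
  m2 <- aggregate_daily_to_monthly(g2)
  jul <- 7
  expect_equal(m2$tmax_abs[jul, 1, 1], 41)
  expect_gt(m2$tmax_abs[jul, 1, 1], m2$tmax[jul, 1, 1])
  expect_equal(m2$tmin_abs[1, 1, 1], 10)
  expect_error(aggregate_daily_to_monthly(m), "already monthly")
})

test_that("months below the completeness threshold become missing", {
  tm <- rep(5, 365)
  tm[1:11] <- NA                                # January: 20/31 valid
  g <- mk_daily_grid(years = 2001, tmean = tm)
  m <- aggregate_daily_to_monthly(g, completeness_threshold = 0.8)
  expect_true(is.na(m$tmean[1, 1, 1]))          # 20/31 < 0.8
  expect_equal(m$tmean[2, 1, 1], 5)
  m2 <- aggregate_daily_to_monthly(g, completeness_threshold = 0.6)
  expect_equal(m2$tmean[1, 1, 1], 5)            # 20/31 >= 0.6
})

test_that("monthly climatology equals the direct per-month mean", {
  # two years, January tmean 0 and 4 -> slot 2
  v <- rep(0, 24); v[1] <- 0; v[13] <- 4
  g <- mk_monthly_grid(years = 2001:2002, tmean = v)
  cl <- monthly_climatology(g)
  expect_equal(cl$tmean[1, 1, 1], 2)
  # identical years repeated -> climatology equals any single year
  gp <- periodic_grid(nlat = 2, nlon = 2, years = 2001:2006)
  clp <- monthly_climatology(gp)
  expect_equal(clp$tmean[, , ], gp$tmean[1:12, , ])
  # random values vs independent per-month mean
  g3 <- random_monthly_grid(nlat = 2, nlon = 2, years = 2001:2005,
                            seed = 3)
  cl3 <- monthly_climatology(g3)
  for (m in 1:12) {
    idx <- seq(m, by = 12, length.out = 5)
    expect_equal(cl3$precip[m, , ],
                 apply(g3$precip[idx, , , drop = FALSE], c(2, 3), mean))
  }
  expect_error(monthly_climatology(g3, period = c(1999, 2005)),
               "outside series coverage")
})

test_that("climatology of monthly aggregates matches per-month means taken
           directly from the daily data", {
  set.seed(5)
  g <- mk_daily_grid(years = 2001:2003, tmean = rnorm(3 * 365, 10, 5))
  cl <- monthly_climatology(aggregate_daily_to_monthly(g))
  yr <- as.POSIXlt(g$time)$year + 1900
  mo <- as.POSIXlt(g$time)$mon + 1
  direct <- sapply(1:12, function(m) {
    mean(sapply(2001:2003, function(y) {
      mean(g$tmean[yr == y & mo == m, 1, 1])
    }))
  })
  expect_equal(as.vector(cl$tmean[, 1, 1]), direct)
})

test_that("quarters crossing the year boundary pull physically adjacent
           months", {
  # wettest block Dec-Feb; window centered Jan 1970 must include Dec 1969
  years <- 1969:1971
  prec <- rep(10, 36)
  names(prec) <- paste(rep(years, each = 12), rep(1:12, 3))
  prec["1969 12"] <- 30
  prec["1970 1"] <- 40
  prec["1970 2"] <- 50
  g <- mk_monthly_grid(years = years, precip = unname(prec),
                       tmean = rep(10, 36))
  w <- quarter_window(1, "consecutive_median")
  expect_equal(w$months, c(12L, 1L, 2L))
  qv <- quarter_values(g, w, year = 1970)
  expect_equal(qv$precip[1, 1], 120)            # 30 + 40 + 50
  expect_equal(qv$temperature[1, 1], 10)        # constant tmean
  expect_false(qv$edge)
  # same-year wrap takes Dec 1970 instead
  wv <- quarter_values(g, quarter_window(1, "same_year_wrap"),
                       year = 1970)
  expect_equal(wv$precip[1, 1], 10 + 40 + 50)
  # first year of the series has no preceding December
  q69 <- quarter_values(g, w, year = 1969)
  expect_true(q69$edge)
  expect_true(is.na(q69$precip[1, 1]))
  expect_error(quarter_values(g, w, year = 1969, edge_policy = "extend"),
               "extend")
})

test_that("quarter precipitation equals a brute-force three-month sliding
           sum for interior years", {
  g <- random_monthly_grid(nlat = 2, nlon = 2, years = 2001:2006,
                           seed = 9)
  yr <- as.POSIXlt(g$time)$year + 1900
  mo <- as.POSIXlt(g$time)$mon + 1
  for (center in c(1, 4, 12)) {
    w <- quarter_window(center, "consecutive_median")
    for (year in 2002:2005) {
      qv <- quarter_values(g, w, year = year)
      mons <- center + c(-1, 0, 1)
      yrs <- year + ifelse(mons < 1, -1, ifelse(mons > 12, 1, 0))
      mons <- ((mons - 1) %% 12) + 1
      brute <- Reduce(`+`, lapply(1:3, function(k) {
        g$precip[which(yr == yrs[k] & mo == mons[k]), , ]
      }))
      expect_equal(qv$precip, matrix(brute, 2, 2))
    }
  }
})

test_that("quarter conventions agree on windows not crossing a year
           boundary", {
  g <- random_monthly_grid(nlat = 2, nlon = 2, years = 2001:2004,
                           seed = 13)
  for (center in 2:11) {
    a <- quarter_values(g, quarter_window(center, "consecutive_median"),
                        year = 2002)
    b <- quarter_values(g, quarter_window(center, "same_year_wrap"),
                        year = 2002)
    expect_equal(a$precip, b$precip)
    expect_equal(a$temperature, b$temperature)
  }
})

test_that("cropping subsets the grid without touching values", {
  g <- random_monthly_grid(nlat = 4, nlon = 6, years = 2001:2002,
                           seed = 2)
  cg <- crop_grid(g, lon_bounds = c(0.5, 1.6), lat_bounds = c(40.4, 41.1))
  expect_equal(cg$lon, g$lon[2:4])
  expect_equal(cg$lat, g$lat[2:3])
  expect_equal(cg$tmean, g$tmean[, 2:3, 2:4, drop = FALSE])
  expect_error(crop_grid(g, lon_bounds = c(90, 95)), "empty crop")
})
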