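test_that("annual mean temperature handles both mean-temperature sources", {
  g <- mk_monthly_grid(years = 2001:2003, tmean = 10)
  expect_equal(bcv1_annual_mean_temperature(g)[1, 1], 10)
  g2 <- mk_monthly_grid(years = 2001:2003, tmin = 5, tmax = 15)
  cfg <- scheme_config(mean_temp_source = "from_minmax")
  expect_equal(bcv1_annual_mean_temperature(g2, cfg)[1, 1], 10)
  expect_error(bcv1_annual_mean_temperature(g2), "direct")
  expect_error(bcv1_annual_mean_temperature(g, cfg), "from_minmax")
})

test_that("direct and min/max-derived means differ on skewed daily data and
           the difference is what explicit averaging gives", {
  set.seed(21)
  nt <- 2 * 365
  tmean <- rnorm(nt, 10, 3)
  # asymmetric diurnal distribution: maxima far above, minima close below
  tmax <- tmean + abs(rnorm(nt, 8, 2))
  tmin <- tmean - abs(rnorm(nt, 2, 0.5))
  g <- mk_daily_grid(years = 2001:2002, tmean = tmean, tmin = tmin,
                     tmax = tmax)
  b_direct <- bcv1_annual_mean_temperature(g)
  b_minmax <- bcv1_annual_mean_temperature(
    g, scheme_config(mean_temp_source = "from_minmax"))
  expect_gt(abs(b_direct[1, 1] - b_minmax[1, 1]), 1)
  # oracle: explicit mean over the generated daily values, month-weighted
  m <- aggregate_daily_to_monthly(g)
  expect_equal(b_direct[1, 1],
               mean(monthly_climatology(m)$tmean[, 1, 1]))
  expect_equal(b_minmax[1, 1],
               mean((monthly_climatology(m)$tmin[, 1, 1] +
                       monthly_climatology(m)$tmax[, 1, 1]) / 2))
})

test_that("diurnal range and seasonality statistics match direct formulas", {
  rng <- rep(c(4, 6, 8), length.out = 12)
  g <- mk_monthly_grid(years = 2001:2002,
                       tmean = 10, tmin = rep(10 - rng / 2, 2),
                       tmax = rep(10 + rng / 2, 2))
  expect_equal(bcv2_mean_diurnal_range(g)[1, 1], 6)
  # sinusoidal monthly means -> 100 x SD of the 12 listed values
  mm <- 10 + 10 * sin(2 * pi * (1:12) / 12)
  gs <- mk_monthly_grid(years = 2001:2003, tmean = rep(mm, 3))
  expect_equal(bcv4_temperature_seasonality(gs)[1, 1], 100 * sd(mm))
  expect_equal(
    bcv4_temperature_seasonality(
      gs, scheme_config(bio4_sd = "population"))[1, 1],
    100 * sd(mm) * sqrt(11 / 12))
  gc <- mk_monthly_grid(years = 2001:2003, tmean = 10)
  expect_equal(bcv4_temperature_seasonality(gc)[1, 1], 0)
  # symmetric tmin/tmax around tmean: both sources identical
  gsym <- mk_monthly_grid(years = 2001:2002, tmean = rep(mm, 2),
                          tmin = rep(mm - 3, 2), tmax = rep(mm + 3, 2))
  expect_equal(
    bcv4_temperature_seasonality(gsym),
    bcv4_temperature_seasonality(
      gsym, scheme_config(mean_temp_source = "from_minmax")))
})

test_that("precipitation seasonality uses the offset coefficient of
           variation", {
  g0 <- mk_monthly_grid(years = 2001:2002, precip = 50, tmean = 10)
  expect_equal(bcv15_precipitation_seasonality(g0)[1, 1], 0)
  gz <- mk_monthly_grid(years = 2001:2002, precip = 0, tmean = 10)
  expect_equal(bcv15_precipitation_seasonality(gz)[1, 1], 0)
  expect_true(is.na(bcv15_precipitation_seasonality(
    gz, scheme_config(bio15_offset = FALSE))[1, 1]))
  slots <- c(rep(0, 11), 120)
  gs <- mk_monthly_grid(years = 2001:2003, precip = rep(slots, 3),
                        tmean = 10)
  expect_equal(bcv15_precipitation_seasonality(gs)[1, 1],
               100 * sd(slots) / (mean(slots) + 1))
})

test_that("POI month selection honors scheme, ties and degeneracy", {
  # peak in July every year: CLIM and BIO modal coincide
  p <- rep(10, 12); p[7] <- 100
  g <- mk_monthly_grid(years = 2001:2004, precip = rep(p, 4), tmean = 10)
  sc <- select_poi_month(g, "precip", "max", scheme_config("CLIM"))
  sb <- select_poi_month(g, "precip", "max", scheme_config("BIO"))
  expect_equal(sc$clim_choice[1, 1], 7L)
  expect_equal(sb$modal_choice[1, 1], 7L)
  expect_equal(poi_agreement_fraction(sc, sb), 1.0)
  # two equal maxima (Mar, Sep) break to the earliest month
  p2 <- rep(10, 12); p2[c(3, 9)] <- 100
  g2 <- mk_monthly_grid(years = 2001:2002, precip = rep(p2, 2),
                        tmean = 10)
  expect_equal(select_poi_month(g2, "precip", "max")$clim_choice[1, 1],
               3L)
  # peak alternating Jun/Aug: per-year alternates, climatology resolves
  # where the mean of the regimes peaks (verified by explicit argmax)
  pj <- rep(10, 12); pj[6] <- 100; pj[7] <- 60
  pa <- rep(10, 12); pa[8] <- 100; pa[7] <- 60
  g3 <- mk_monthly_grid(years = 2001:2004,
                        precip = rep(c(pj, pa), 2), tmean = 10)
  s3 <- select_poi_month(g3, "precip", "max", scheme_config("BIO"))
  expect_equal(as.vector(s3$per_year_choice[, 1, 1]),
               c(6L, 8L, 6L, 8L))
  clim <- sapply(1:12, function(m) mean(c(pj[m], pa[m])))
  expect_equal(s3$clim_choice[1, 1], which.max(clim))
  expect_equal(s3$clim_choice[1, 1], 7L)
  # flat precipitation: degenerate flag, month 1
  gflat <- mk_monthly_grid(years = 2001:2002, precip = 5, tmean = 10)
  sf <- select_poi_month(gflat, "precip", "max")
  expect_equal(sf$clim_choice[1, 1], 1L)
  expect_true(sf$degenerate[1, 1])
})

test_that("POI quarter selection scans all center months and respects the
           year boundary", {
  p <- c(10, 10, 10, 100, 100, 100, rep(10, 6))
  g <- mk_monthly_grid(years = 2001:2003, precip = rep(p, 3), tmean = 10)
  expect_equal(select_poi_quarter(g, "precip", "max")$clim_choice[1, 1],
               5L)
  # wettest block Dec-Feb -> center January
  p2 <- rep(10, 12); p2[c(12, 1, 2)] <- 90
  g2 <- mk_monthly_grid(years = 2001:2004, precip = rep(p2, 4),
                        tmean = 10)
  s2 <- select_poi_quarter(g2, "precip", "max",
                           scheme_config(poi_scheme = "BIO"))
  expect_equal(s2$modal_choice[1, 1], 1L)
  expect_equal(s2$clim_choice[1, 1], 1L)
  # randomized series vs exhaustive 12-window sliding-sum oracle
  g3 <- random_monthly_grid(nlat = 3, nlon = 2, years = 2001:2006,
                            seed = 31)
  s3 <- select_poi_quarter(g3, "precip", "max", scheme_config("CLIM"))
  cl <- monthly_climatology(g3)
  for (i in 1:3) for (j in 1:2) {
    sums <- sapply(1:12, function(cc) {
      mons <- ((cc + c(-1, 0, 1) - 1) %% 12) + 1
      sum(cl$precip[mons, i, j])
    })
    expect_equal(s3$clim_choice[i, j], which.max(sums))
  }
})

test_that("absolute and mean extreme schemes differ exactly as constructed", {
  # every July day 30 C: schemes agree
  tmax <- rep(20, 365); tmax[182:212] <- 30
  g <- mk_daily_grid(years = 2001, tmax = tmax, tmin = tmax - 10)
  m <- aggregate_daily_to_monthly(g)
  v_mean <- bcv_extreme_month_temperature(
    m, "warmest", scheme_config(extreme_scheme = "mean"))
  v_abs <- bcv_extreme_month_temperature(
    m, "warmest", scheme_config(extreme_scheme = "absolute"))
  expect_equal(v_mean$value[1, 1], 30)
  expect_equal(v_abs$value[1, 1], 30)
  # one 41 C day inside a 25 C July: mean 25, absolute 41 (16 C gap, the
  # oceanic-regime magnitude class)
  tmax2 <- rep(15, 365); tmax2[182:212] <- 25; tmax2[196] <- 41
  g2 <- mk_daily_grid(years = 2001, tmax = tmax2, tmin = tmax2 - 10)
  m2 <- aggregate_daily_to_monthly(g2)
  v_mean2 <- bcv_extreme_month_temperature(
    m2, "warmest", scheme_config(extreme_scheme = "mean"))
  v_abs2 <- bcv_extreme_month_temperature(
    m2, "warmest", scheme_config(extreme_scheme = "absolute"))
  expect_equal(v_mean2$value[1, 1], 25 + 16 / 31)
  expect_equal(v_abs2$value[1, 1], 41)
  expect_gt(v_abs2$value[1, 1] - v_mean2$value[1, 1], 15)
  # monthly-only input cannot serve the absolute scheme
  g3 <- mk_monthly_grid(years = 2001:2002, tmax = 20, tmin = 10)
  expect_error(
    bcv_extreme_month_temperature(
      g3, "warmest", scheme_config(extreme_scheme = "absolute")),
    "absolute")
})

test_that("mean-max and absolute-max months can disagree; both values match
           an exhaustive (month, year) scan", {
  # mean maximum peaks in July; a single August day holds the absolute max
  set.seed(41)
  years <- 2001:2003
  time <- seq(as.Date("2001-01-01"), as.Date("2003-12-31"), by = "day")
  mo <- as.POSIXlt(time)$mon + 1
  tmax <- 15 + 10 * cos(2 * pi * (mo - 7) / 12) + rnorm(length(time), 0, 1)
  tmax[which(mo == 8)[20]] <- 45
  g <- mk_daily_grid(years = years, tmax = array(tmax, c(length(time), 1, 1)),
                     tmin = array(tmax - 8, c(length(time), 1, 1)))
  m <- aggregate_daily_to_monthly(g)
  r_mean <- bcv_extreme_month_temperature(
    m, "warmest", scheme_config(extreme_scheme = "mean"))
  r_abs <- bcv_extreme_month_temperature(
    m, "warmest", scheme_config(extreme_scheme = "absolute"))
  expect_equal(r_mean$selection$clim_choice[1, 1], 7L)
  expect_equal(r_abs$selection$clim_choice[1, 1], 8L)
  # brute-force scan over all (month, year) cells
  yr <- as.POSIXlt(m$time)$year + 1900
  mo_m <- as.POSIXlt(m$time)$mon + 1
  expect_equal(r_abs$value[1, 1], max(m$tmax_abs[, 1, 1]))
  clim_tmax <- sapply(1:12, function(mm) mean(m$tmax[mo_m == mm, 1, 1]))
  expect_equal(r_mean$value[1, 1], max(clim_tmax))
})

test_that("monthly precipitation extremes obey the order-statistic bound
           and match brute force", {
  gp <- periodic_grid(years = 2001:2006)
  rc <- bcv_monthly_precip_extremes(gp, scheme_config("CLIM"))
  rb <- bcv_monthly_precip_extremes(gp, scheme_config("BIO"))
  expect_equal(rc$bio13, rb$bio13)              # periodic input: BIO = CLIM
  expect_equal(rc$bio14, rb$bio14)
  g <- random_monthly_grid(nlat = 3, nlon = 3, years = 2001:2008,
                           seed = 51)
  rc <- bcv_monthly_precip_extremes(g, scheme_config("CLIM"))
  rb <- bcv_monthly_precip_extremes(g, scheme_config("BIO"))
  expect_true(all(rb$bio13 >= rc$bio13))
  expect_true(all(rb$bio14 <= rc$bio14))
  expect_true(all(rb$bio14 >= 0))
  # brute-force recomputation from first principles
  yr <- as.POSIXlt(g$time)$year + 1900
  mo <- as.POSIXlt(g$time)$mon + 1
  for (i in 1:3) for (j in 1:3) {
    per_year_max <- sapply(2001:2008, function(y) {
      max(g$precip[yr == y, i, j])
    })
    expect_equal(rb$bio13[i, j], mean(per_year_max))
    clim <- sapply(1:12, function(m) mean(g$precip[mo == m, i, j]))
    expect_equal(rc$bio13[i, j], max(clim))
  }
})

test_that("co-phased temperature and precipitation make the warmest and
           wettest quarters coincide", {
  mm <- 1:12
  tm <- 10 + 8 * cos(2 * pi * (mm - 7) / 12)
  pr <- 50 + 40 * cos(2 * pi * (mm - 7) / 12)
  g <- mk_monthly_grid(years = 2001:2004, tmean = rep(tm, 4),
                       precip = rep(pr, 4))
  q <- bcv_quarter_variables(g)
  expect_equal(q$wettest$clim_choice, q$warmest$clim_choice)
  expect_equal(q$bio8, q$bio10)
})

test_that("the full 19-variable suite satisfies its internal identities and
           scheme limits", {
  g <- random_monthly_grid(nlat = 4, nlon = 3, years = 2001:2010,
                           seed = 61)
  for (scheme in c("CLIM", "BIO")) {
    res <- compute_all_bcvs(g, scheme_config(poi_scheme = scheme))
    v <- res$values
    expect_equal(v$bio7, v$bio5 - v$bio6)
    expect_equal(v$bio3, 100 * v$bio2 / v$bio7)
    expect_true(all(v$bio5 >= v$bio6))
    expect_true(all(v$bio10 >= v$bio11))
    expect_true(all(v$bio13 >= v$bio14))
    expect_true(all(v$bio14 >= 0))
    expect_true(all(v$bio16 >= v$bio17))
    expect_true(all(v$bio17 >= 0))
    expect_true(all(v$bio16 <= v$bio12 + 1e-9))
    expect_length(res$failures, 0)
  }
  # exactly periodic input: whole stacks identical between schemes
  gp <- periodic_grid(years = 2001:2008)
  rc <- compute_all_bcvs(gp, scheme_config("CLIM"))
  rb <- compute_all_bcvs(gp, scheme_config("BIO"))
  for (nm in paste0("bio", 1:19)) {
    expect_equal(rb$values[[nm]], rc$values[[nm]])
  }
})

test_that("per-variable failures yield missing layers, not a global abort", {
  g <- mk_monthly_grid(years = 2001:2003, tmean = 10 + sin(1:36))
  res <- compute_all_bcvs(g)   # no tmin/tmax/precip at all
  expect_s3_class(res, "bcv_result")
  expect_false(anyNA(res$values$bio1))
  expect_true(all(is.na(res$values$bio2)))
  expect_true(all(is.na(res$values$bio12)))
  expect_true(all(c("bio2", "bio5", "bio12") %in% names(res$failures)))
})
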