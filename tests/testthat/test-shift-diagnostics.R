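test_that("circular month distance wraps the calendar", {
  expect_equal(circular_month_distance(1, 12), 1L)
  expect_equal(circular_month_distance(2, 8), 6L)
  expect_equal(circular_month_distance(5, 5), 0L)
  m <- sample(1:12, 50, replace = TRUE)
  n <- sample(1:12, 50, replace = TRUE)
  expect_true(all(circular_month_distance(m, n) <= 6))
  expect_equal(circular_month_distance(m, n),
               circular_month_distance(n, m))
  expect_error(circular_month_distance(0, 5), "1..12")
  expect_error(circular_month_distance(1, 13), "1..12")
})

test_that("an injected heat spike produces the constructed timing shift", {
  # seasonal mean peak in July; single spike two months later
  spec <- synthetic_climate_spec(
    nlon = 2, nlat = 2, years = c(2001, 2010), daily = TRUE,
    noise_sd_temp = 0, noise_sd_precip = 0, peak_jitter_sd = 0,
    trend = 0, temp_peak_month = 7,
    heat_spike = list(offset_months = 2, magnitude = 16), seed = 3)
  g <- generate_daily_series(spec)
  m <- aggregate_daily_to_monthly(g)
  shift <- extreme_timing_shift(m)
  expect_true(all(shift == 2L))
  # no spike, no noise: absolute and mean maxima coincide
  spec0 <- synthetic_climate_spec(
    nlon = 2, nlat = 2, years = c(2001, 2010), daily = TRUE,
    noise_sd_temp = 0, noise_sd_precip = 0, peak_jitter_sd = 0,
    trend = 0, seed = 3)
  m0 <- aggregate_daily_to_monthly(generate_daily_series(spec0))
  expect_true(all(extreme_timing_shift(m0) == 0L))
  expect_true(all(shift_induced_temperature_difference(m0) == 0))
  # spikes can also sit before the seasonal peak: negative shift
  spec_neg <- synthetic_climate_spec(
    nlon = 1, nlat = 1, years = c(2001, 2010), daily = TRUE,
    noise_sd_temp = 0, noise_sd_precip = 0, peak_jitter_sd = 0,
    trend = 0, heat_spike = list(offset_months = -3, magnitude = 16),
    seed = 3)
  m_neg <- aggregate_daily_to_monthly(generate_daily_series(spec_neg))
  expect_equal(extreme_timing_shift(m_neg)[1, 1], -3L)
  # circular bound on random data
  g_r <- random_monthly_grid(nlat = 3, nlon = 3, years = 2001:2005,
                             seed = 8)
  g_r$tmax_abs <- g_r$tmax + 2
  expect_true(all(abs(extreme_timing_shift(g_r)) <= 6))
})

test_that("the shift-induced temperature difference follows the sinusoid
           closed form and is never positive", {
  # monthly climatology A*cos(2pi (m - p)/12); absolute max forced one
  # month after the mean peak -> difference A (cos(pi/6) - 1)
  A <- 10; p <- 7
  mm <- 1:12
  tmax <- 20 + A * cos(2 * pi * (mm - p) / 12)
  tmax_abs <- tmax
  tmax_abs[p + 1] <- max(tmax) + 5   # absolute max lands on month p+1
  g <- mk_monthly_grid(years = 2001:2003, tmax = rep(tmax, 3),
                       tmax_abs = rep(tmax_abs, 3),
                       tmin = rep(tmax - 8, 3))
  expect_equal(extreme_timing_shift(g)[1, 1], 1L)
  expect_equal(shift_induced_temperature_difference(g)[1, 1],
               A * (cos(pi / 6) - 1), tolerance = 1e-12)
  # property: <= 0 whatever the data (mean-max month maximizes the series)
  for (seed in 1:5) {
    gr <- random_monthly_grid(nlat = 2, nlon = 2, years = 2001:2004,
                              seed = seed)
    gr$tmax_abs <- gr$tmax + abs(gr$tmean)
    expect_true(all(shift_induced_temperature_difference(gr) <= 1e-12))
  }
})

test_that("interannual POI shift measures known jitter and is invariant to
           the year-axis origin", {
  # alternating centers Mar/May, modal reference Mar -> mean 1.0 month
  p1 <- rep(10, 12); p1[3] <- 100
  p2 <- rep(10, 12); p2[5] <- 100
  g <- mk_monthly_grid(years = 2001:2006,
                       precip = rep(c(p1, p2), 3), tmean = 10)
  sel <- select_poi_month(g, "precip", "max",
                          scheme_config(poi_scheme = "BIO"))
  r <- interannual_poi_shift(sel, "modal")
  expect_equal(r$mean_shift[1, 1], 1.0)
  # distance to the climatological choice as alternative reference
  rc <- interannual_poi_shift(sel, "climatological")
  expect_equal(rc$mean_shift[1, 1], 1.0)
  # same quarter every year -> 0
  gp <- periodic_grid(years = 2001:2006)
  selp <- select_poi_quarter(gp, "precip", "max",
                             scheme_config(poi_scheme = "BIO"))
  rp <- interannual_poi_shift(selp, "modal")
  expect_true(all(rp$mean_shift == 0))
  # relabeling the year axis leaves the statistic unchanged
  g2 <- g; g2$time <- mk_time_monthly(2011:2016)
  sel2 <- select_poi_month(g2, "precip", "max",
                           scheme_config(poi_scheme = "BIO"))
  expect_equal(interannual_poi_shift(sel2, "modal")$mean_shift,
               r$mean_shift)
  expect_error(interannual_poi_shift(
    select_poi_month(g, "precip", "max", scheme_config("CLIM"))),
    "BIO")
})

test_that("jittered peaks reproduce the analytic expected circular
           distance", {
  sigma <- 1.2
  spec <- synthetic_climate_spec(
    nlon = 1, nlat = 1, years = c(1901, 2100), peak_months = 7,
    peak_sharpness = 4, peak_jitter_sd = sigma, noise_sd_precip = 0,
    noise_sd_temp = 0, trend = 0, seed = 17)
  g <- generate_monthly_series(spec)
  sel <- select_poi_month(g, "precip", "max",
                          scheme_config(poi_scheme = "BIO"))
  # selections recover the constructed truth exactly
  truth <- ((g$attrs$true_peak_months[, 1] - 1L) %% 12L) + 1L
  expect_equal(as.vector(sel$per_year_choice[, 1, 1]), as.vector(truth))
  r <- interannual_poi_shift(sel, "modal")
  # analytic expectation of circ(round(N(0, sigma))) on the 12-month circle
  k <- -30:30
  pk <- pnorm(k + 0.5, 0, sigma) - pnorm(k - 0.5, 0, sigma)
  dk <- pmin(abs(k) %% 12, 12 - abs(k) %% 12)
  mu <- sum(pk * dk)
  se <- sqrt(sum(pk * dk^2) - mu^2) / sqrt(200)
  expect_lt(abs(r$mean_shift[1, 1] - mu), 3 * se)
})

test_that("agreement fractions count matching labels over the mask", {
  p <- rep(10, 12); p[7] <- 100
  g <- mk_monthly_grid(years = 2001:2004, nlat = 2, nlon = 5,
                       precip = rep(p, 4), tmean = 10)
  a <- select_poi_month(g, "precip", "max", scheme_config("CLIM"))
  b <- select_poi_month(g, "precip", "max", scheme_config("BIO"))
  expect_equal(poi_agreement_fraction(a, b), 1.0)
  # engineer 4 disagreements among 10 boxes -> 0.6
  b2 <- b
  b2$modal_choice[1, 1:4] <- 9L
  expect_equal(poi_agreement_fraction(a, b2), 0.6)
  expect_equal(poi_agreement_fraction(b2, a), 0.6)   # symmetric
  mask <- matrix(FALSE, 2, 5); mask[2, ] <- TRUE
  expect_equal(poi_agreement_fraction(a, b2, mask), 1.0)
  wrong <- select_poi_month(g, "precip", "min", scheme_config("CLIM"))
  expect_error(poi_agreement_fraction(a, wrong), "objective")
})
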