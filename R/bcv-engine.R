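#' @title Engine internals
#' @description Internal helpers shared by the BCV operations: monthly
#'   cubes `[12, year, space]`, climatologies, quarter cubes, and
#'   tie-broken argmax/argmin selection (earliest calendar month wins).
#' @name engine-internals
#' @keywords internal
NULL

# monthly cube [12, nY, nspace] for one variable over the period years
eng_cube <- function(series, var, yrs) {
  arr <- series[[var]]
  if (is.null(arr)) return(NULL)
  nY <- length(yrs); ns <- n_space(series)
  m <- as_ts_matrix(arr)
  yr <- time_year(series$time); mo <- time_month(series$time)
  cube <- array(NA_real_, dim = c(12L, nY, ns))
  keep <- which(yr >= yrs[1L] & yr <= yrs[nY])
  cube[cbind(rep(mo[keep], ns),
             rep(match(yr[keep], yrs), ns),
             rep(seq_len(ns), each = length(keep)))] <- as.vector(m[keep, ])
  cube
}

# single-month slice [nspace] for (year, month), NULL when not covered
eng_month_slice <- function(series, var, year, month) {
  arr <- series[[var]]
  if (is.null(arr)) return(NULL)
  yr <- time_year(series$time); mo <- time_month(series$time)
  j <- which(yr == year & mo == month)
  if (!length(j)) return(NULL)
  as.vector(as_ts_matrix(arr)[j[1L], ])
}

# climatology [12, nspace] from a cube; mean over contributing years
clim_over_years <- function(cube) {
  dm <- dim(cube)
  a <- aperm(cube, c(2L, 1L, 3L))
  dim(a) <- c(dm[2L], dm[1L] * dm[3L])
  cl <- colMeans(a, na.rm = TRUE)
  cl[colSums(!is.na(a)) == 0L] <- NA_real_
  matrix(cl, dm[1L], dm[3L])
}

# earliest-tie argmax/argmin over rows of a [12, N] matrix
arg_ext <- function(m, direction) {
  mm <- if (direction == "min") -m else m
  mm[is.na(mm)] <- -Inf
  idx <- max.col(t(mm), ties.method = "first")
  idx[colSums(is.finite(mm)) == 0L] <- NA_integer_
  idx
}

# m[idx[j], j] with NA-safe indexing
value_at <- function(m, idx) {
  out <- rep(NA_real_, length(idx))
  ok <- !is.na(idx)
  out[ok] <- m[cbind(idx[ok], which(ok))]
  out
}

# most frequent per-year month index per column; earliest month on ties
modal_of <- function(per_year) {
  counts <- vapply(1:12, function(m) colSums(per_year == m, na.rm = TRUE),
                   numeric(ncol(per_year)))
  counts <- matrix(t(counts), 12L, ncol(per_year))
  idx <- max.col(t(counts), ties.method = "first")
  idx[colSums(counts) == 0L] <- NA_integer_
  idx
}

eng_build <- function(series, config) {
  stopifnot(inherits(series, "climate_grid"),
            inherits(config, "scheme_config"))
  if (series$step == "daily") {
    series <- aggregate_daily_to_monthly(series,
                                         config$completeness_threshold)
  }
  yr <- time_year(series$time)
  period <- if (is.null(config$period)) range(yr) else config$period
  if (period[1L] < min(yr) || period[2L] > max(yr)) {
    stop(sprintf("period %d-%d outside series coverage %d-%d",
                 period[1L], period[2L], min(yr), max(yr)), call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  env$series <- series
  env$cfg <- config
  env$yrs <- period[1L]:period[2L]
  env$nla <- length(series$lat); env$nlo <- length(series$lon)
  env$ns <- n_space(series)
  env$cubes <- list()
  env
}

ctx_cube <- function(ctx, var) {
  if (var == "tmean_use") return(ctx_tmean_cube(ctx))
  if (is.null(ctx$cubes[[var]])) {
    cube <- eng_cube(ctx$series, var, ctx$yrs)
    if (is.null(cube)) {
      stop(sprintf("variable '%s' is required but absent from the series",
                   var), call. = FALSE)
    }
    ctx$cubes[[var]] <- cube
  }
  ctx$cubes[[var]]
}

ctx_tmean_cube <- function(ctx) {
  if (!is.null(ctx$cubes$tmean_use)) return(ctx$cubes$tmean_use)
  cfg <- ctx$cfg
  cube <- if (cfg$mean_temp_source == "direct") {
    if (is.null(ctx$series$tmean)) {
      stop("mean_temp_source='direct' requires a tmean variable",
           call. = FALSE)
    }
    ctx_cube(ctx, "tmean")
  } else {
    if (is.null(ctx$series$tmin) || is.null(ctx$series$tmax)) {
      stop("mean_temp_source='from_minmax' requires tmin and tmax",
           call. = FALSE)
    }
    (ctx_cube(ctx, "tmin") + ctx_cube(ctx, "tmax")) / 2
  }
  ctx$cubes$tmean_use <- cube
  cube
}

# December of (start-1) and January of (end+1), for boundary quarters
ctx_edge_slice <- function(ctx, var, side) {
  if (var == "tmean_use" && ctx$cfg$mean_temp_source == "from_minmax") {
    a <- ctx_edge_slice(ctx, "tmin", side)
    b <- ctx_edge_slice(ctx, "tmax", side)
    return(if (is.null(a) || is.null(b)) NULL else (a + b) / 2)
  }
  v <- if (var == "tmean_use") "tmean" else var
  if (side == "prev") {
    eng_month_slice(ctx$series, v, ctx$yrs[1L] - 1L, 12L)
  } else {
    eng_month_slice(ctx$series, v, ctx$yrs[length(ctx$yrs)] + 1L, 1L)
  }
}

# quarter cube [12 centers, nY, nspace]: mean for temperature-like
# variables, sum for precipitation; NA outside usable years
eng_qcube <- function(ctx, var, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  key <- paste0("q_", var, "_", stat)
  if (!is.null(ctx$cubes[[key]])) return(ctx$cubes[[key]])
  cfg <- ctx$cfg
  cube <- ctx_cube(ctx, var)
  nY <- length(ctx$yrs); ns <- ctx$ns
  consec <- cfg$quarter_convention == "consecutive_median"
  prev_dec <- if (consec) ctx_edge_slice(ctx, var, "prev")
  next_jan <- if (consec) ctx_edge_slice(ctx, var, "next")
  usable <- rep(TRUE, nY)
  if (consec) {
    if (is.null(prev_dec)) usable[1L] <- FALSE
    if (is.null(next_jan)) usable[nY] <- FALSE
    if (cfg$edge_policy == "extend" && !all(usable)) {
      stop(paste0("edge_policy='extend' requires the series to cover one ",
                  "extra month on each side of the period for boundary ",
                  "quarters"), call. = FALSE)
    }
  }
  member <- function(mon, off) {
    # [nY, ns] slice of month `mon` at year offset `off`
    s <- matrix(NA_real_, nY, ns)
    src_years <- seq_len(nY) + off
    inside <- src_years >= 1L & src_years <= nY
    s[inside, ] <- matrix(cube[mon, src_years[inside], ], sum(inside), ns)
    if (any(!inside)) {
      if (off == -1L && !is.null(prev_dec)) s[1L, ] <- prev_dec
      if (off == +1L && !is.null(next_jan)) s[nY, ] <- next_jan
    }
    s
  }
  Q <- array(NA_real_, dim = c(12L, nY, ns))
  for (cm in 1:12) {
    w <- quarter_window(cm, cfg$quarter_convention)
    offs <- quarter_year_offsets(w)
    s1 <- member(w$months[1L], offs[1L])
    s2 <- member(w$months[2L], offs[2L])
    s3 <- member(w$months[3L], offs[3L])
    Q[cm, , ] <- if (stat == "mean") (s1 + s2 + s3) / 3 else s1 + s2 + s3
  }
  Q[, !usable, ] <- NA_real_
  attr(Q, "usable_years") <- usable
  ctx$cubes[[key]] <- Q
  Q
}

new_poi_selection <- function(ctx, kind, variable, direction, clim_choice,
                              per_year = NULL, modal = NULL,
                              degenerate = NULL) {
  shape <- function(v) {
    if (is.null(v)) return(NULL)
    matrix(v, ctx$nla, ctx$nlo)
  }
  structure(
    list(kind = kind,
         objective = list(variable = variable, direction = direction),
         scheme = ctx$cfg$poi_scheme,
         clim_choice = shape(clim_choice),
         per_year_choice = if (!is.null(per_year)) {
           array(per_year, dim = c(nrow(per_year), ctx$nla, ctx$nlo))
         },
         modal_choice = shape(modal),
         degenerate = shape(degenerate),
         years = ctx$yrs,
         lon = ctx$series$lon, lat = ctx$series$lat),
    class = "poi_selection")
}

#' @export
print.poi_selection <- function(x, ...) {
  cat(sprintf("<poi_selection> %s %s of %s (%s scheme), %d x %d boxes\n",
              x$objective$direction, x$kind, x$objective$variable,
              x$scheme, length(x$lat), length(x$lon)))
  invisible(x)
}

#' Representative POI labels of a selection
#'
#' Returns the per-gridbox month (or quarter center month) that labels the
#' selection: the climatological choice for the CLIM scheme and the modal
#' (most frequent per-year) choice for the BIO scheme.
#'
#' @param sel a `poi_selection`.
#' @return integer matrix `[lat, lon]` of months 1-12.
#' @export
poi_labels <- function(sel) {
  stopifnot(inherits(sel, "poi_selection"))
  if (sel$scheme == "BIO" && !is.null(sel$modal_choice)) {
    sel$modal_choice
  } else {
    sel$clim_choice
  }
}

# circular quarter values of a monthly climatology [12, ns]
qclim_of <- function(cl, stat) {
  out <- matrix(NA_real_, 12L, ncol(cl))
  for (cm in 1:12) {
    mons <- ((cm + c(-1L, 0L, 1L) - 1L) %% 12L) + 1L
    s <- cl[mons[1L], ] + cl[mons[2L], ] + cl[mons[3L], ]
    out[cm, ] <- if (stat == "mean") s / 3 else s
  }
  out
}

# selection + per-scheme value on a monthly cube; used for both month POIs
# and (with a quarter cube) quarter POIs. `clim` overrides the
# climatological 12-slot evaluation (quarters evaluate circularly on the
# monthly climatology rather than on averaged per-year windows).
eng_select <- function(ctx, cube, kind, variable, direction, clim = NULL) {
  nY <- dim(cube)[2L]; ns <- dim(cube)[3L]
  cl <- if (is.null(clim)) clim_over_years(cube) else clim
  clim_choice <- arg_ext(cl, direction)
  rng <- apply(cl, 2L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA else diff(range(v))
  })
  degenerate <- !is.na(rng) & rng == 0
  per_year <- modal <- NULL
  if (ctx$cfg$poi_scheme == "BIO") {
    flat <- cube; dim(flat) <- c(12L, nY * ns)
    per_year <- matrix(arg_ext(flat, direction), nY, ns)
    modal <- modal_of(per_year)
  }
  sel <- new_poi_selection(ctx, kind, variable, direction, clim_choice,
                           per_year, modal, degenerate)
  list(sel = sel, clim = cl, clim_choice = clim_choice,
       per_year = per_year, cube = cube)
}

# scheme-consistent value of a selected POI: CLIM = climatology at the
# fixed choice; BIO = per-year value at the per-year choice, averaged
eng_value <- function(ctx, slc) {
  if (ctx$cfg$poi_scheme == "CLIM") {
    return(value_at(slc$clim, slc$clim_choice))
  }
  nY <- dim(slc$cube)[2L]; ns <- dim(slc$cube)[3L]
  flat <- slc$cube; dim(flat) <- c(12L, nY * ns)
  v <- matrix(value_at(flat, as.vector(slc$per_year)), nY, ns)
  out <- colMeans(v, na.rm = TRUE)
  out[colSums(!is.na(v)) == 0L] <- NA_real_
  out
}

#' Select the period-of-interest month
#'
#' Identifies the wettest/driest/warmest/coldest calendar month per grid
#' box. Under the CLIM scheme the month is the argmax/argmin of the 12
#' whole-period climatological slots; under the BIO scheme it is selected
#' separately within each year (the modal per-year month is also
#' reported). Ties break to the earliest calendar month. Grid boxes whose
#' climatology is flat (e.g. zero precipitation all year) select month 1
#' and are flagged degenerate.
#'
#' @param series a [climate_grid()] (daily input is aggregated first).
#' @param variable which monthly series drives the objective (`"precip"`,
#'   `"tmean"`, `"tmax"`, `"tmin"`, `"tmax_abs"`, `"tmin_abs"`).
#' @param direction `"max"` or `"min"`.
#' @param config a [scheme_config()].
#' @return a `poi_selection`.
#' @export
select_poi_month <- function(series, variable = "precip",
                             direction = c("max", "min"),
                             config = scheme_config()) {
  direction <- match.arg(direction)
  ctx <- eng_build(series, config)
  cube <- ctx_cube(ctx, variable)
  eng_select(ctx, cube, "month", variable, direction)$sel
}

#' Select the period-of-interest quarter
#'
#' Evaluates all 12 candidate quarters (three consecutive months labeled
#' by the center month; see [quarter_window()]) on quarter mean
#' temperature or quarter precipitation sum and picks the extreme one per
#' grid box, under the CLIM or BIO scheme of `config`.
#'
#' @inheritParams select_poi_month
#' @param variable `"precip"` (quarter sums) or `"tmean"` (quarter means,
#'   sourced per `config$mean_temp_source`).
#' @return a `poi_selection` with `kind = "quarter"`; choices are center
#'   months.
#' @export
select_poi_quarter <- function(series, variable = c("precip", "tmean"),
                               direction = c("max", "min"),
                               config = scheme_config()) {
  variable <- match.arg(variable)
  direction <- match.arg(direction)
  ctx <- eng_build(series, config)
  v <- if (variable == "tmean") "tmean_use" else "precip"
  stat <- if (variable == "precip") "sum" else "mean"
  Q <- eng_qcube(ctx, v, stat)
  qcl <- qclim_of(clim_over_years(ctx_cube(ctx, v)), stat)
  eng_select(ctx, Q, "quarter", variable, direction, clim = qcl)$sel
}

#' Annual mean temperature (BIO1)
#'
#' Mean of the 12 climatological monthly mean temperatures, with the mean
#' temperature either taken directly from the dataset or computed as
#' `(tmin + tmax) / 2` at native resolution, per
#' `config$mean_temp_source`.
#'
#' @inheritParams select_poi_month
#' @return numeric matrix `[lat, lon]`, degrees C.
#' @export
bcv1_annual_mean_temperature <- function(series, config = scheme_config()) {
  ctx <- eng_build(series, config)
  cl <- clim_over_years(ctx_tmean_cube(ctx))
  out <- colMeans(cl, na.rm = TRUE)
  out[colSums(!is.na(cl)) == 0L] <- NA_real_
  matrix(out, ctx$nla, ctx$nlo)
}

#' Mean diurnal range (BIO2)
#'
#' Mean over the 12 climatological months of (monthly mean daily maximum
#' minus monthly mean daily minimum temperature).
#'
#' @inheritParams select_poi_month
#' @return numeric matrix `[lat, lon]`, degrees C.
#' @export
bcv2_mean_diurnal_range <- function(series, config = scheme_config()) {
  ctx <- eng_build(series, config)
  cl <- clim_over_years(ctx_cube(ctx, "tmax")) -
    clim_over_years(ctx_cube(ctx, "tmin"))
  out <- colMeans(cl, na.rm = TRUE)
  out[colSums(!is.na(cl)) == 0L] <- NA_real_
  matrix(out, ctx$nla, ctx$nlo)
}

#' Temperature seasonality (BIO4)
#'
#' 100 times the standard deviation of the 12 climatological monthly mean
#' temperatures (sample SD by default; see `scheme_config(bio4_sd=)`).
#' Boxes with fewer than two valid monthly slots are missing.
#'
#' @inheritParams select_poi_month
#' @return numeric matrix `[lat, lon]`, degrees C x 100.
#' @export
bcv4_temperature_seasonality <- function(series, config = scheme_config()) {
  ctx <- eng_build(series, config)
  cl <- clim_over_years(ctx_tmean_cube(ctx))
  matrix(slot_sd(cl, ctx$cfg$bio4_sd) * 100, ctx$nla, ctx$nlo)
}

slot_sd <- function(cl, kind = "sample") {
  nv <- colSums(!is.na(cl))
  s <- apply(cl, 2L, stats::sd, na.rm = TRUE)
  if (kind == "population") s <- s * sqrt((nv - 1) / nv)
  s[nv < 2L] <- NA_real_
  s
}

#' Precipitation seasonality (BIO15)
#'
#' Coefficient of variation of the 12 climatological monthly precipitation
#' sums, in percent: `100 * sd / (mean + 1)` with the +1 mm offset on by
#' default so that all-dry grid boxes return 0 instead of dividing by
#' zero (`scheme_config(bio15_offset=)`).
#'
#' @inheritParams select_poi_month
#' @return numeric matrix `[lat, lon]`, percent.
#' @export
bcv15_precipitation_seasonality <- function(series,
                                            config = scheme_config()) {
  ctx <- eng_build(series, config)
  cl <- clim_over_years(ctx_cube(ctx, "precip"))
  s <- slot_sd(cl, "sample")
  mu <- colMeans(cl, na.rm = TRUE)
  mu[colSums(!is.na(cl)) == 0L] <- NA_real_
  den <- if (ctx$cfg$bio15_offset) mu + 1 else mu
  out <- 100 * s / den
  out[!is.na(den) & den == 0] <- NA_real_
  matrix(out, ctx$nla, ctx$nlo)
}

# engine core for BIO5/BIO6 under both extreme schemes
eng_extreme_month <- function(ctx, which) {
  cfg <- ctx$cfg
  direction <- if (which == "warmest") "max" else "min"
  base_var <- if (which == "warmest") "tmax" else "tmin"
  if (cfg$extreme_scheme == "absolute") {
    abs_var <- if (which == "warmest") "tmax_abs" else "tmin_abs"
    if (is.null(ctx$series[[abs_var]])) {
      stop(paste0("extreme_scheme='absolute' needs per-month absolute ",
                  "daily extremes (", abs_var, "); provide daily input or ",
                  "a grid produced by aggregate_daily_to_monthly()"),
           call. = FALSE)
    }
    cube <- ctx_cube(ctx, abs_var)
    if (cfg$poi_scheme == "CLIM") {
      # pool across years: the period-wide absolute extreme of each
      # calendar month, then the extreme month of the pooled values
      nY <- dim(cube)[2L]
      a <- aperm(cube, c(2L, 1L, 3L))
      dim(a) <- c(nY, 12L * ctx$ns)
      pooled <- suppressWarnings(
        if (direction == "max") apply(a, 2L, max, na.rm = TRUE)
        else apply(a, 2L, min, na.rm = TRUE))
      pooled[!is.finite(pooled)] <- NA_real_
      pooled <- matrix(pooled, 12L, ctx$ns)
      choice <- arg_ext(pooled, direction)
      sel <- new_poi_selection(ctx, "month", abs_var, direction, choice)
      return(list(value = value_at(pooled, choice), sel = sel))
    }
    slc <- eng_select(ctx, cube, "month", abs_var, direction)
    return(list(value = eng_value(ctx, slc), sel = slc$sel))
  }
  slc <- eng_select(ctx, ctx_cube(ctx, base_var), "month", base_var,
                    direction)
  list(value = eng_value(ctx, slc), sel = slc$sel)
}

#' Extreme-month temperature (BIO5 / BIO6)
#'
#' Maximum temperature of the warmest month (`which = "warmest"`, BIO5) or
#' minimum temperature of the coldest month (`"coldest"`, BIO6). Under the
#' `mean` extreme scheme the monthly series of mean daily maxima/minima is
#' used both to locate the month and as its value; under the `absolute`
#' scheme the month's single most extreme daily value is used (requiring
#' daily-derived monthly absolute extremes). CLIM pools/averages across
#' all years' instances of the fixed calendar month; BIO selects per year
#' and averages the per-year values.
#'
#' @inheritParams select_poi_month
#' @param which `"warmest"` or `"coldest"`.
#' @return list with `value` (matrix `[lat, lon]`, degrees C) and
#'   `selection` (a `poi_selection`).
#' @export
bcv_extreme_month_temperature <- function(series,
                                          which = c("warmest", "coldest"),
                                          config = scheme_config()) {
  which <- match.arg(which)
  ctx <- eng_build(series, config)
  r <- eng_extreme_month(ctx, which)
  list(value = matrix(r$value, ctx$nla, ctx$nlo), selection = r$sel)
}

#' Wettest/driest month precipitation (BIO13 / BIO14)
#'
#' Precipitation of the wettest (BIO13) and driest (BIO14) month. CLIM
#' takes the climatology slot of the month selected on the climatology;
#' BIO averages each year's own extreme month value.
#'
#' @inheritParams select_poi_month
#' @return list with matrices `bio13`, `bio14` (mm) and the two
#'   `poi_selection`s.
#' @export
bcv_monthly_precip_extremes <- function(series, config = scheme_config()) {
  ctx <- eng_build(series, config)
  cube <- ctx_cube(ctx, "precip")
  wet <- eng_select(ctx, cube, "month", "precip", "max")
  dry <- eng_select(ctx, cube, "month", "precip", "min")
  list(bio13 = matrix(eng_value(ctx, wet), ctx$nla, ctx$nlo),
       bio14 = matrix(eng_value(ctx, dry), ctx$nla, ctx$nlo),
       wettest = wet$sel, driest = dry$sel)
}

#' Quarter-based bioclimatic variables (BIO8-BIO11, BIO16-BIO19)
#'
#' Selects the wettest, driest, warmest and coldest quarters (see
#' [select_poi_quarter()]) and evaluates mean temperature and
#' precipitation on them: BIO8/BIO9 = mean temperature of the wettest/
#' driest quarter, BIO10/BIO11 = mean temperature of the warmest/coldest
#' quarter, BIO16/BIO17 = precipitation of the wettest/driest quarter,
#' BIO18/BIO19 = precipitation of the warmest/coldest quarter.
#'
#' @inheritParams select_poi_month
#' @return list of eight value matrices (`bio8` ... `bio19`) and four
#'   `poi_selection`s (`wettest`, `driest`, `warmest`, `coldest`).
#' @export
bcv_quarter_variables <- function(series, config = scheme_config()) {
  ctx <- eng_build(series, config)
  r <- eng_quarters(ctx)
  for (nm in grep("^bio", names(r), value = TRUE)) {
    r[[nm]] <- matrix(r[[nm]], ctx$nla, ctx$nlo)
  }
  r
}

eng_quarters <- function(ctx) {
  Qt <- eng_qcube(ctx, "tmean_use", "mean")
  Qp <- eng_qcube(ctx, "precip", "sum")
  qt_cl <- qclim_of(clim_over_years(ctx_tmean_cube(ctx)), "mean")
  qp_cl <- qclim_of(clim_over_years(ctx_cube(ctx, "precip")), "sum")
  wet <- eng_select(ctx, Qp, "quarter", "precip", "max", clim = qp_cl)
  dry <- eng_select(ctx, Qp, "quarter", "precip", "min", clim = qp_cl)
  hot <- eng_select(ctx, Qt, "quarter", "tmean", "max", clim = qt_cl)
  cold <- eng_select(ctx, Qt, "quarter", "tmean", "min", clim = qt_cl)
  # value of the companion variable on an already-selected quarter
  other <- function(slc, cube, clim) {
    eng_value(ctx, list(clim = clim, clim_choice = slc$clim_choice,
                        per_year = slc$per_year, cube = cube))
  }
  list(bio8 = other(wet, Qt, qt_cl), bio9 = other(dry, Qt, qt_cl),
       bio10 = eng_value(ctx, hot), bio11 = eng_value(ctx, cold),
       bio16 = eng_value(ctx, wet), bio17 = eng_value(ctx, dry),
       bio18 = other(hot, Qp, qp_cl), bio19 = other(cold, Qp, qp_cl),
       wettest = wet$sel, driest = dry$sel,
       warmest = hot$sel, coldest = cold$sel)
}

#' Compute all 19 bioclimatic variables
#'
#' Runs the full BIO1-BIO19 suite under an explicit [scheme_config()],
#' sharing one set of POI selections across variables (BIO3 and BIO7 are
#' derived from the already-selected BIO5/BIO6). Daily input is first
#' aggregated to monthly resolution. A failure of an individual variable
#' (e.g. requesting absolute extremes without daily-derived data) yields a
#' missing layer for that variable, never a global abort.
#'
#' @inheritParams select_poi_month
#' @return an object of class `bcv_result`: named list `values`
#'   (`bio1` ... `bio19`, matrices `[lat, lon]`), the POI selections, the
#'   `scheme_config` used, grid coordinates and any per-variable failure
#'   messages.
#' @export
compute_all_bcvs <- function(series, config = scheme_config()) {
  ctx <- eng_build(series, config)
  nla <- ctx$nla; nlo <- ctx$nlo
  blank <- matrix(NA_real_, nla, nlo)
  values <- stats::setNames(rep(list(blank), 19L), paste0("bio", 1:19))
  poi <- list()
  failures <- list()
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  v <- grab("bio1", {
    cl <- clim_over_years(ctx_tmean_cube(ctx))
    out <- colMeans(cl, na.rm = TRUE)
    out[colSums(!is.na(cl)) == 0L] <- NA_real_
    out
  })
  if (!is.null(v)) values$bio1 <- matrix(v, nla, nlo)

  cl_range <- grab("bio2", {
    clim_over_years(ctx_cube(ctx, "tmax")) -
      clim_over_years(ctx_cube(ctx, "tmin"))
  })
  if (!is.null(cl_range)) {
    out <- colMeans(cl_range, na.rm = TRUE)
    out[colSums(!is.na(cl_range)) == 0L] <- NA_real_
    values$bio2 <- matrix(out, nla, nlo)
  }

  v <- grab("bio4", {
    slot_sd(clim_over_years(ctx_tmean_cube(ctx)), config$bio4_sd) * 100
  })
  if (!is.null(v)) values$bio4 <- matrix(v, nla, nlo)

  hot <- grab("bio5", eng_extreme_month(ctx, "warmest"))
  if (!is.null(hot)) {
    values$bio5 <- matrix(hot$value, nla, nlo)
    poi$warmest_month <- hot$sel
  }
  cold <- grab("bio6", eng_extreme_month(ctx, "coldest"))
  if (!is.null(cold)) {
    values$bio6 <- matrix(cold$value, nla, nlo)
    poi$coldest_month <- cold$sel
  }
  values$bio7 <- values$bio5 - values$bio6
  values$bio3 <- 100 * values$bio2 / values$bio7
  values$bio3[!is.na(values$bio7) & values$bio7 <= 0] <- NA_real_

  pr <- grab("bio12", {
    cl <- clim_over_years(ctx_cube(ctx, "precip"))
    colSums(cl)   # NA if any climatological slot is missing
  })
  if (!is.null(pr)) values$bio12 <- matrix(pr, nla, nlo)

  pm <- grab("bio13", {
    cube <- ctx_cube(ctx, "precip")
    wet <- eng_select(ctx, cube, "month", "precip", "max")
    dry <- eng_select(ctx, cube, "month", "precip", "min")
    list(w = wet, d = dry)
  })
  if (!is.null(pm)) {
    values$bio13 <- matrix(eng_value(ctx, pm$w), nla, nlo)
    values$bio14 <- matrix(eng_value(ctx, pm$d), nla, nlo)
    poi$wettest_month <- pm$w$sel
    poi$driest_month <- pm$d$sel
  }

  v <- grab("bio15", {
    cl <- clim_over_years(ctx_cube(ctx, "precip"))
    s <- slot_sd(cl, "sample")
    mu <- colMeans(cl, na.rm = TRUE)
    mu[colSums(!is.na(cl)) == 0L] <- NA_real_
    den <- if (config$bio15_offset) mu + 1 else mu
    out <- 100 * s / den
    out[!is.na(den) & den == 0] <- NA_real_
    out
  })
  if (!is.null(v)) values$bio15 <- matrix(v, nla, nlo)

  qr <- grab("bio8", eng_quarters(ctx))
  if (!is.null(qr)) {
    for (nm in c("bio8", "bio9", "bio10", "bio11",
                 "bio16", "bio17", "bio18", "bio19")) {
      values[[nm]] <- matrix(qr[[nm]], nla, nlo)
    }
    poi$wettest_quarter <- qr$wettest
    poi$driest_quarter <- qr$driest
    poi$warmest_quarter <- qr$warmest
    poi$coldest_quarter <- qr$coldest
  }

  structure(
    list(values = values, poi = poi, config = config,
         lon = ctx$series$lon, lat = ctx$series$lat,
         land_mask = ctx$series$land_mask,
         period = range(ctx$yrs), failures = failures,
         provenance = "computed"),
    class = "bcv_result")
}

#' @export
print.bcv_result <- function(x, ...) {
  cat(sprintf("<bcv_result> 19 variables, %d x %d boxes, period %d-%d\n",
              length(x$lat), length(x$lon), x$period[1L], x$period[2L]))
  cat(sprintf("  scheme: %s / %s extremes / tmean %s / %s quarters\n",
              x$config$poi_scheme, x$config$extreme_scheme,
              x$config$mean_temp_source, x$config$quarter_convention))
  if (length(x$failures)) {
    cat("  missing layers:", paste(names(x$failures), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Units of the 19 bioclimatic variables
#'
#' @return named character vector, `bio1` ... `bio19`.
#' @export
bcv_units <- function() {
  c(bio1 = "degC", bio2 = "degC", bio3 = "percent", bio4 = "degC*100",
    bio5 = "degC", bio6 = "degC", bio7 = "degC", bio8 = "degC",
    bio9 = "degC", bio10 = "degC", bio11 = "degC", bio12 = "mm",
    bio13 = "mm", bio14 = "mm", bio15 = "percent", bio16 = "mm",
    bio17 = "mm", bio18 = "mm", bio19 = "mm")
}
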