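#' Gridded climate time series
#'
#' `climate_grid()` is the universal input container of bcvcalc: a regular
#' lon/lat grid carrying time series of daily or monthly minimum, mean and
#' maximum 2m temperature (degrees C) and precipitation totals (mm).
#' Monthly grids may additionally carry the per-month absolute daily
#' extremes (`tmax_abs`, `tmin_abs`) produced by
#' [aggregate_daily_to_monthly()], which the absolute-extreme calculation
#' scheme requires.
#'
#' All data arrays are dimensioned `[time, lat, lon]`. Missing values are
#' `NA`. Latitudes and longitudes must be strictly ascending; the time axis
#' must be strictly increasing with a uniform daily or monthly step.
#'
#' @param lon numeric vector of grid-box center longitudes (degrees east,
#'   ascending).
#' @param lat numeric vector of grid-box center latitudes (degrees north,
#'   ascending).
#' @param time `Date` vector; for monthly data, the first day of each month.
#' @param tmin,tmax,tmean,precip optional arrays `[time, lat, lon]`;
#'   temperatures in degrees C, precipitation totals in mm per time step.
#' @param tmax_abs,tmin_abs optional arrays of per-month absolute daily
#'   maxima of `tmax` / minima of `tmin` (monthly grids only).
#' @param land_mask optional logical matrix `[lat, lon]`; defaults to all
#'   `TRUE`.
#' @param attrs free-form provenance list.
#' @return an object of class `climate_grid`.
#' @export
climate_grid <- function(lon, lat, time, tmin = NULL, tmax = NULL,
                         tmean = NULL, precip = NULL,
                         tmax_abs = NULL, tmin_abs = NULL,
                         land_mask = NULL, attrs = list()) {
  time <- as.Date(time)
  step <- infer_time_step(time)
  if (is.null(land_mask)) {
    land_mask <- matrix(TRUE, length(lat), length(lon))
  }
  x <- structure(
    list(lon = as.numeric(lon), lat = as.numeric(lat), time = time,
         step = step, tmin = tmin, tmax = tmax, tmean = tmean,
         precip = precip, tmax_abs = tmax_abs, tmin_abs = tmin_abs,
         land_mask = land_mask, attrs = attrs),
    class = "climate_grid")
  validate_climate_grid(x)
  x
}

# Uniform-step detection: "daily" (1-day spacing) or "monthly"
# (consecutive first-of-month stamps). Anything else is rejected.
infer_time_step <- function(time) {
  if (length(time) == 0L) stop("empty time axis", call. = FALSE)
  if (anyDuplicated(time)) stop("duplicate time stamps", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("time axis must be strictly increasing", call. = FALSE)
  }
  if (length(time) == 1L) {
    return(if (format(time, "%d") == "01") "monthly" else "daily")
  }
  d <- diff(as.integer(time))
  if (all(d == 1L)) return("daily")
  lt <- as.POSIXlt(time)
  idx <- (lt$year + 1900L) * 12L + lt$mon
  if (all(diff(idx) == 1L) && all(lt$mday == 1L)) return("monthly")
  stop("time axis is neither uniformly daily nor consecutive first-of-month",
       call. = FALSE)
}

validate_climate_grid <- function(x) {
  nt <- length(x$time); nla <- length(x$lat); nlo <- length(x$lon)
  if (nla > 1 && is.unsorted(x$lat, strictly = TRUE)) {
    stop("lat must be strictly ascending", call. = FALSE)
  }
  if (nlo > 1 && is.unsorted(x$lon, strictly = TRUE)) {
    stop("lon must be strictly ascending", call. = FALSE)
  }
  vars <- c("tmin", "tmax", "tmean", "precip", "tmax_abs", "tmin_abs")
  present <- vars[!vapply(x[vars], is.null, logical(1))]
  if (!length(intersect(present, c("tmin", "tmax", "tmean", "precip")))) {
    stop("at least one of tmin/tmax/tmean/precip must be present",
         call. = FALSE)
  }
  for (v in present) {
    dm <- dim(x[[v]])
    if (is.null(dm) || length(dm) != 3L || any(dm != c(nt, nla, nlo))) {
      stop(sprintf("%s must be an array [time=%d, lat=%d, lon=%d]",
                   v, nt, nla, nlo), call. = FALSE)
    }
  }
  if (x$step == "daily" && (!is.null(x$tmax_abs) || !is.null(x$tmin_abs))) {
    stop("tmax_abs/tmin_abs are monthly summaries; not valid on daily grids",
         call. = FALSE)
  }
  if (!is.null(x$tmin) && !is.null(x$tmax)) {
    bad <- x$tmin > x$tmax
    if (any(bad, na.rm = TRUE)) {
      stop("tmin > tmax at some non-missing grid points", call. = FALSE)
    }
  }
  if (!is.null(x$precip) && any(x$precip < 0, na.rm = TRUE)) {
    stop("negative precipitation values", call. = FALSE)
  }
  if (!all(dim(x$land_mask) == c(nla, nlo))) {
    stop("land_mask must be [lat, lon]", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.climate_grid <- function(x, ...) {
  vars <- c("tmin", "tmax", "tmean", "precip", "tmax_abs", "tmin_abs")
  present <- vars[!vapply(x[vars], is.null, logical(1))]
  cat(sprintf("<climate_grid> %s, %d x %d boxes, %d steps (%s to %s)\n",
              x$step, length(x$lat), length(x$lon), length(x$time),
              format(min(x$time)), format(max(x$time))))
  cat("  variables:", paste(present, collapse = ", "), "\n")
  invisible(x)
}

grid_vars <- function(x) {
  vars <- c("tmin", "tmax", "tmean", "precip", "tmax_abs", "tmin_abs")
  vars[!vapply(x[vars], is.null, logical(1))]
}

n_space <- function(x) length(x$lat) * length(x$lon)

time_year  <- function(time) as.POSIXlt(time)$year + 1900L
time_month <- function(time) as.POSIXlt(time)$mon + 1L

# days in a Gregorian calendar month, leap-aware
days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  nxt <- as.Date(ifelse(month == 12L,
                        sprintf("%04d-01-01", year + 1L),
                        sprintf("%04d-%02d-01", year, month + 1L)))
  as.integer(nxt - first)
}

# view a [time, lat, lon] array as [time, space]
as_ts_matrix <- function(arr) {
  dm <- dim(arr)
  dim(arr) <- c(dm[1L], dm[2L] * dm[3L])
  arr
}

#' Aggregate a daily grid to monthly resolution
#'
#' Temperatures are averaged and precipitation is summed over each calendar
#' month. A month is flagged missing when fewer than
#' `completeness_threshold` of its days carry non-missing values (the 80%
#' completeness convention of station-based gridded datasets). The result
#' additionally carries the per-month absolute daily maximum of `tmax`
#' (`tmax_abs`) and absolute daily minimum of `tmin` (`tmin_abs`), which
#' the absolute-extreme calculation scheme consumes.
#'
#' @param series a daily [climate_grid()].
#' @param completeness_threshold fraction in (0, 1]; default 0.8.
#' @return a monthly `climate_grid`.
#' @export
aggregate_daily_to_monthly <- function(series, completeness_threshold = 0.8) {
  stopifnot(inherits(series, "climate_grid"))
  if (series$step != "daily") {
    stop("input is already monthly; aggregation needs a daily grid",
         call. = FALSE)
  }
  if (completeness_threshold <= 0 || completeness_threshold > 1) {
    stop("completeness_threshold must be in (0, 1]", call. = FALSE)
  }
  yr <- time_year(series$time); mo <- time_month(series$time)
  key <- yr * 12L + (mo - 1L)
  ukey <- sort(unique(key))
  grp <- match(key, ukey)
  nm <- length(ukey)
  uyr <- ukey %/% 12L; umo <- ukey %% 12L + 1L
  ndays <- days_in_month(uyr, umo)
  need <- completeness_threshold * ndays
  nla <- length(series$lat); nlo <- length(series$lon); ns <- nla * nlo

  agg <- function(arr, fun) {
    m <- as_ts_matrix(arr)
    out <- matrix(NA_real_, nm, ns)
    nval <- rowsum((!is.na(m)) + 0, grp)
    for (g in seq_len(nm)) {
      rows <- m[grp == g, , drop = FALSE]
      out[g, ] <- fun(rows)
    }
    out[nval < need] <- NA_real_
    array(out, dim = c(nm, nla, nlo))
  }
  cmean <- function(rows) colMeans(rows, na.rm = TRUE)
  csum  <- function(rows) colSums(rows, na.rm = TRUE)
  cmax  <- function(rows) suppressWarnings(apply(rows, 2L, max, na.rm = TRUE))
  cmin  <- function(rows) suppressWarnings(apply(rows, 2L, min, na.rm = TRUE))

  res <- list()
  if (!is.null(series$tmin))  res$tmin  <- agg(series$tmin, cmean)
  if (!is.null(series$tmax))  res$tmax  <- agg(series$tmax, cmean)
  if (!is.null(series$tmean)) res$tmean <- agg(series$tmean, cmean)
  if (!is.null(series$precip)) res$precip <- agg(series$precip, csum)
  if (!is.null(series$tmax))  res$tmax_abs <- agg(series$tmax, cmax)
  if (!is.null(series$tmin))  res$tmin_abs <- agg(series$tmin, cmin)
  for (v in names(res)) res[[v]][!is.finite(res[[v]])] <- NA_real_

  climate_grid(
    lon = series$lon, lat = series$lat,
    time = as.Date(sprintf("%04d-%02d-01", uyr, umo)),
    tmin = res$tmin, tmax = res$tmax, tmean = res$tmean,
    precip = res$precip, tmax_abs = res$tmax_abs, tmin_abs = res$tmin_abs,
    land_mask = series$land_mask,
    attrs = c(series$attrs,
              list(aggregated_from = "daily",
                   completeness_threshold = completeness_threshold)))
}

#' Monthly climatology of a gridded series
#'
#' Reduces a monthly series to 12 climatological monthly mean values per
#' variable per grid box: slot `m` is the arithmetic mean of all
#' non-missing month-`m` values inside `period`. A slot is missing only
#' when no year contributes.
#'
#' @param series a monthly [climate_grid()].
#' @param period integer `c(start_year, end_year)`; defaults to the full
#'   years covered by the series.
#' @return an object of class `climatology_grid` with arrays
#'   `[12, lat, lon]` per variable plus `n_years` counts.
#' @export
monthly_climatology <- function(series, period = NULL) {
  stopifnot(inherits(series, "climate_grid"))
  if (series$step != "monthly") {
    stop("monthly_climatology needs a monthly grid; aggregate first",
         call. = FALSE)
  }
  yr <- time_year(series$time); mo <- time_month(series$time)
  if (is.null(period)) period <- range(yr)
  period <- as.integer(period)
  if (period[1L] > period[2L]) stop("empty period", call. = FALSE)
  if (period[1L] < min(yr) || period[2L] > max(yr)) {
    stop(sprintf("period %d-%d outside series coverage %d-%d",
                 period[1L], period[2L], min(yr), max(yr)), call. = FALSE)
  }
  keep <- yr >= period[1L] & yr <= period[2L]
  nla <- length(series$lat); nlo <- length(series$lon); ns <- nla * nlo
  out <- list(lon = series$lon, lat = series$lat, period = period,
              land_mask = series$land_mask)
  mo_k <- mo[keep]
  n_years <- NULL
  for (v in grid_vars(series)) {
    m <- as_ts_matrix(series[[v]])[keep, , drop = FALSE]
    slot <- matrix(NA_real_, 12L, ns)
    cnt <- matrix(0L, 12L, ns)
    for (mm in 1:12) {
      rows <- m[mo_k == mm, , drop = FALSE]
      if (nrow(rows)) {
        nv <- colSums(!is.na(rows))
        mu <- colMeans(rows, na.rm = TRUE)
        mu[nv == 0L] <- NA_real_
        slot[mm, ] <- mu
        cnt[mm, ] <- nv
      }
    }
    out[[v]] <- array(slot, dim = c(12L, nla, nlo))
    if (is.null(n_years)) n_years <- array(cnt, dim = c(12L, nla, nlo))
  }
  out$n_years <- n_years
  structure(out, class = "climatology_grid")
}

#' @export
print.climatology_grid <- function(x, ...) {
  vars <- intersect(c("tmin", "tmax", "tmean", "precip",
                      "tmax_abs", "tmin_abs"), names(x))
  vars <- vars[!vapply(x[vars], is.null, logical(1))]
  cat(sprintf("<climatology_grid> %d x %d boxes, period %d-%d\n",
              length(x$lat), length(x$lon), x$period[1L], x$period[2L]))
  cat("  variables:", paste(vars, collapse = ", "), "\n")
  invisible(x)
}

#' Three-month quarter window
#'
#' A quarter is three consecutive calendar months labeled by the middle
#' (median) month. Under the `consecutive_median` convention the window
#' for center month `m` of year `y` is `(m-1, m, m+1)` with months taken
#' from the physically preceding/following year where the window crosses a
#' year boundary (the first quarter of 1970 is December 1969 - February
#' 1970). Under `same_year_wrap` all three months are taken from the same
#' calendar year (the November quarter of year `y` uses January of `y`),
#' the behavior of climatology-oriented implementations.
#'
#' @param center_month integer 1-12.
#' @param convention `"consecutive_median"` or `"same_year_wrap"`.
#' @return an object of class `quarter_window`.
#' @export
quarter_window <- function(center_month,
                           convention = c("consecutive_median",
                                          "same_year_wrap")) {
  convention <- match.arg(convention)
  center_month <- as.integer(center_month)
  if (is.na(center_month) || center_month < 1L || center_month > 12L) {
    stop("center_month must be in 1..12", call. = FALSE)
  }
  months <- ((center_month + c(-1L, 0L, 1L) - 1L) %% 12L) + 1L
  structure(list(center_month = center_month, months = months,
                 convention = convention),
            class = "quarter_window")
}

# year offset of each window member relative to the center month's year
# under consecutive_median: -1 for a December pulled before January, +1 for
# a January pulled after December, else 0.
quarter_year_offsets <- function(window) {
  if (window$convention == "same_year_wrap") return(c(0L, 0L, 0L))
  c(if (window$months[1L] > window$center_month) -1L else 0L,
    0L,
    if (window$months[3L] < window$center_month) 1L else 0L)
}

#' Quarter mean temperature and precipitation sum
#'
#' Evaluates a [quarter_window()] either on a [monthly_climatology()]
#' (circular over the 12 slots) or on a monthly [climate_grid()] for a
#' specific `year`. Quarter temperature is the mean of the three monthly
#' mean temperatures; quarter precipitation is the sum of the three monthly
#' sums. Any missing member month makes the quarter missing.
#'
#' @param x a `climate_grid` (monthly) or `climatology_grid`.
#' @param window a [quarter_window()].
#' @param year calendar year of the center month (required for series).
#' @param edge_policy what to do when a member month falls outside series
#'   coverage: `"extend"` requires the data to be there (error otherwise),
#'   `"drop-edge-year"` and `"strict-missing"` return `NA` for the affected
#'   boxes (an `edge` attribute flags the case).
#' @return list with matrices `temperature` and `precip` (`[lat, lon]`;
#'   `NULL` when the underlying variable is absent), plus an `edge` flag.
#' @export
quarter_values <- function(x, window, year = NULL,
                           edge_policy = c("drop-edge-year", "extend",
                                           "strict-missing")) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(inherits(window, "quarter_window"))
  if (inherits(x, "climatology_grid")) {
    tm <- if (!is.null(x$tmean)) {
      (x$tmean[window$months[1L], , ] + x$tmean[window$months[2L], , ] +
         x$tmean[window$months[3L], , ]) / 3
    }
    pr <- if (!is.null(x$precip)) {
      x$precip[window$months[1L], , ] + x$precip[window$months[2L], , ] +
        x$precip[window$months[3L], , ]
    }
    return(list(temperature = as_field(tm, x), precip = as_field(pr, x),
                edge = FALSE))
  }
  stopifnot(inherits(x, "climate_grid"))
  if (x$step != "monthly") stop("quarter_values needs monthly data",
                                call. = FALSE)
  if (is.null(year)) stop("year is required for series input", call. = FALSE)
  offs <- quarter_year_offsets(window)
  yr <- time_year(x$time); mo <- time_month(x$time)
  idx <- vapply(1:3, function(i) {
    j <- which(yr == year + offs[i] & mo == window$months[i])
    if (length(j)) j[1L] else NA_integer_
  }, integer(1))
  edge <- anyNA(idx)
  if (edge && edge_policy == "extend") {
    stop(sprintf(paste0("quarter centered on month %d of %d needs months ",
                        "outside series coverage; extend the series by one ",
                        "year or choose another edge_policy"),
                 window$center_month, year), call. = FALSE)
  }
  pick <- function(v) {
    if (is.null(x[[v]])) return(NULL)
    if (edge) {
      return(matrix(NA_real_, length(x$lat), length(x$lon)))
    }
    x[[v]][idx[1L], , ] + x[[v]][idx[2L], , ] + x[[v]][idx[3L], , ]
  }
  tm <- pick("tmean"); if (!is.null(tm)) tm <- tm / 3
  list(temperature = as_field(tm, x), precip = as_field(pick("precip"), x),
       edge = edge)
}

# coerce a possibly-degenerate slice to a [lat, lon] matrix
as_field <- function(v, grid) {
  if (is.null(v)) return(NULL)
  matrix(v, length(grid$lat), length(grid$lon))
}

#' Crop a gridded series to lon/lat bounds
#'
#' Trivial subsetting on the existing grid; no interpolation or regridding.
#'
#' @param series a [climate_grid()].
#' @param lon_bounds,lat_bounds numeric length-2 inclusive bounds; `NULL`
#'   keeps the full extent.
#' @return a `climate_grid` on the subset grid.
#' @export
crop_grid <- function(series, lon_bounds = NULL, lat_bounds = NULL) {
  stopifnot(inherits(series, "climate_grid"))
  ilo <- if (is.null(lon_bounds)) seq_along(series$lon) else {
    which(series$lon >= lon_bounds[1L] & series$lon <= lon_bounds[2L])
  }
  ila <- if (is.null(lat_bounds)) seq_along(series$lat) else {
    which(series$lat >= lat_bounds[1L] & series$lat <= lat_bounds[2L])
  }
  if (!length(ilo) || !length(ila)) stop("empty crop", call. = FALSE)
  out <- series
  out$lon <- series$lon[ilo]; out$lat <- series$lat[ila]
  for (v in grid_vars(series)) {
    out[[v]] <- series[[v]][, ila, ilo, drop = FALSE]
  }
  out$land_mask <- series$land_mask[ila, ilo, drop = FALSE]
  validate_climate_grid(out)
  out
}

#' Restrict a monthly series to a span of calendar years
#'
#' @param series a [climate_grid()].
#' @param years integer `c(start, end)`.
#' @param pad_months months of extra coverage to keep on each side (used to
#'   feed quarters that cross the period boundary).
#' @return a `climate_grid`.
#' @export
subset_years <- function(series, years, pad_months = 0L) {
  stopifnot(inherits(series, "climate_grid"))
  lo <- as.Date(sprintf("%04d-01-01", years[1L]))
  hi <- as.Date(sprintf("%04d-12-31", years[2L]))
  if (pad_months > 0L) {
    lo <- seq(lo, by = sprintf("-%d months", pad_months), length.out = 2)[2L]
    hi <- seq(hi, by = sprintf("%d months", pad_months), length.out = 2)[2L]
  }
  keep <- series$time >= lo & series$time <= hi
  if (!any(keep)) stop("no time steps inside requested years", call. = FALSE)
  out <- series
  out$time <- series$time[keep]
  for (v in grid_vars(series)) {
    out[[v]] <- series[[v]][keep, , , drop = FALSE]
  }
  validate_climate_grid(out)
  out
}
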