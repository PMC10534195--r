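#' Circular distance between calendar months
#'
#' Shortest distance around the 12-month calendar circle,
#' `min(|a-b|, 12-|a-b|)`, always in 0..6. Vectorized; `NA` propagates.
#'
#' @param a,b integer months 1-12.
#' @return integer months.
#' @export
circular_month_distance <- function(a, b) {
  ok <- function(x) all(is.na(x) | (x >= 1 & x <= 12 & x == round(x)))
  if (!ok(a) || !ok(b)) stop("month indices must be in 1..12", call. = FALSE)
  d <- abs(a - b)
  as.integer(pmin(d, 12 - d))
}

# signed circular offset b relative to a, in months; positive = b later.
# Range -5..+6; the antipodal (6-month) case is reported as +6.
signed_month_offset <- function(a, b) {
  ((b - a + 5L) %% 12L) - 5L
}

# month of the climatological mean maximum and month of the period-wide
# absolute maximum of daily tmax, as [lat, lon] matrices
extreme_months <- function(series, period = NULL) {
  stopifnot(inherits(series, "climate_grid"))
  if (series$step == "daily") {
    series <- aggregate_daily_to_monthly(series)
  }
  if (is.null(series$tmax) || is.null(series$tmax_abs)) {
    stop(paste0("needs monthly mean (tmax) and absolute (tmax_abs) daily ",
                "maxima; aggregate a daily series first"), call. = FALSE)
  }
  cfg <- scheme_config(period = period)
  ctx <- eng_build(series, cfg)
  cl_mean <- clim_over_years(ctx_cube(ctx, "tmax"))
  m_mean <- arg_ext(cl_mean, "max")
  cube_abs <- ctx_cube(ctx, "tmax_abs")
  nY <- dim(cube_abs)[2L]
  a <- aperm(cube_abs, c(2L, 1L, 3L))
  dim(a) <- c(nY, 12L * ctx$ns)
  pooled <- suppressWarnings(apply(a, 2L, max, na.rm = TRUE))
  pooled[!is.finite(pooled)] <- NA_real_
  pooled <- matrix(pooled, 12L, ctx$ns)
  m_abs <- arg_ext(pooled, "max")
  list(mean_month = matrix(m_mean, ctx$nla, ctx$nlo),
       abs_month = matrix(m_abs, ctx$nla, ctx$nlo),
       clim_mean = cl_mean, ctx = ctx)
}

#' Timing shift between absolute and mean temperature maxima
#'
#' For each grid box, the signed circular offset (months) between the
#' calendar month holding the period-wide absolute daily maximum
#' temperature and the month of the maximum climatological monthly mean
#' daily maximum. Positive values mean the absolute maximum occurs later
#' in the year than the mean maximum; the antipodal 6-month case is
#' reported as +6.
#'
#' @param series a daily [climate_grid()] or a monthly one carrying
#'   `tmax` and `tmax_abs` (see [aggregate_daily_to_monthly()]).
#' @param period optional `c(start_year, end_year)`.
#' @return integer matrix `[lat, lon]` of signed month offsets.
#' @export
extreme_timing_shift <- function(series, period = NULL) {
  em <- extreme_months(series, period)
  out <- signed_month_offset(em$mean_month, em$abs_month)
  matrix(as.integer(out), nrow(em$mean_month), ncol(em$mean_month))
}

#' Temperature difference induced by the extreme-timing shift
#'
#' Isolates the effect of the timing shift alone: both the month of the
#' period-wide absolute maximum and the month of the climatological mean
#' maximum are fixed from the whole period, and the climatological
#' monthly-mean daily maximum is extracted at both; the difference
#' (absolute-max month minus mean-max month) is returned. It is `<= 0` by
#' construction, since the mean-max month maximizes the mean series.
#'
#' @inheritParams extreme_timing_shift
#' @return numeric matrix `[lat, lon]`, degrees C.
#' @export
shift_induced_temperature_difference <- function(series, period = NULL) {
  em <- extreme_months(series, period)
  v <- value_at(em$clim_mean, as.vector(em$abs_month)) -
    value_at(em$clim_mean, as.vector(em$mean_month))
  matrix(v, nrow(em$mean_month), ncol(em$mean_month))
}

#' Interannual variability of a year-by-year POI selection
#'
#' Mean (over years) circular month distance between each year's selected
#' month/quarter center and a fixed per-gridbox reference: the modal
#' per-year choice (default, the convention used when mapping the most
#' frequent wettest quarter), the climatological choice, or the previous
#' year's choice (`"consecutive"`). Also reports the domain maximum with
#' its location (earliest scan position on ties, scanning latitudes
#' fastest).
#'
#' @param selection a `poi_selection` produced under the BIO scheme.
#' @param reference `"modal"`, `"climatological"` or `"consecutive"`.
#' @return list with `mean_shift` (matrix, months), `max_shift` (scalar),
#'   and `max_location` (list with `lon`, `lat`).
#' @export
interannual_poi_shift <- function(selection,
                                  reference = c("modal", "climatological",
                                                "consecutive")) {
  reference <- match.arg(reference)
  stopifnot(inherits(selection, "poi_selection"))
  if (is.null(selection$per_year_choice)) {
    stop("selection has no per-year choices; run under the BIO scheme",
         call. = FALSE)
  }
  py <- selection$per_year_choice
  nY <- dim(py)[1L]; nla <- dim(py)[2L]; nlo <- dim(py)[3L]
  py <- matrix(py, nY, nla * nlo)
  if (reference == "consecutive") {
    if (nY < 2L) stop("consecutive reference needs >= 2 years",
                      call. = FALSE)
    d <- matrix(NA_real_, nY - 1L, ncol(py))
    for (t in seq_len(nY - 1L)) {
      d[t, ] <- circular_month_distance(py[t, ], py[t + 1L, ])
    }
  } else {
    ref <- if (reference == "modal") {
      if (is.null(selection$modal_choice)) {
        stop("selection has no modal choice", call. = FALSE)
      }
      as.vector(selection$modal_choice)
    } else {
      as.vector(selection$clim_choice)
    }
    d <- matrix(NA_real_, nY, ncol(py))
    for (t in seq_len(nY)) {
      d[t, ] <- circular_month_distance(py[t, ], ref)
    }
  }
  mean_shift <- colMeans(d, na.rm = TRUE)
  mean_shift[colSums(!is.na(d)) == 0L] <- NA_real_
  ms <- matrix(mean_shift, nla, nlo)
  if (all(is.na(ms))) {
    return(list(mean_shift = ms, max_shift = NA_real_,
                max_location = list(lon = NA_real_, lat = NA_real_)))
  }
  j <- which.max(ifelse(is.na(mean_shift), -Inf, mean_shift))
  ila <- (j - 1L) %% nla + 1L
  ilo <- (j - 1L) %/% nla + 1L
  list(mean_shift = ms, max_shift = mean_shift[j],
       max_location = list(lon = selection$lon[ilo],
                           lat = selection$lat[ila]))
}

#' Agreement fraction between two POI selections
#'
#' Fraction of (masked) grid boxes where two selections label the same
#' month or quarter center: the CLIM choice for a CLIM-scheme selection
#' and the modal per-year choice for a BIO-scheme one (see
#' [poi_labels()]). Symmetric in its two arguments.
#'
#' @param selA,selB `poi_selection`s of the same kind and objective on the
#'   same grid.
#' @param mask optional logical matrix `[lat, lon]` restricting the
#'   comparison (e.g. a land or study-area mask).
#' @return fraction in 0..1 (`NA` when no usable boxes).
#' @export
poi_agreement_fraction <- function(selA, selB, mask = NULL) {
  stopifnot(inherits(selA, "poi_selection"),
            inherits(selB, "poi_selection"))
  if (selA$kind != selB$kind ||
      selA$objective$variable != selB$objective$variable ||
      selA$objective$direction != selB$objective$direction) {
    stop("selections differ in kind or objective", call. = FALSE)
  }
  if (!isTRUE(all.equal(selA$lon, selB$lon)) ||
      !isTRUE(all.equal(selA$lat, selB$lat))) {
    stop("selections are on different grids", call. = FALSE)
  }
  a <- poi_labels(selA); b <- poi_labels(selB)
  use <- !is.na(a) & !is.na(b)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(a)))
    use <- use & mask
  }
  if (!any(use)) return(NA_real_)
  mean(a[use] == b[use])
}
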