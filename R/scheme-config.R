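#' Calculation-scheme configuration
#'
#' The 19 standard bioclimatic variables have no single canonical recipe:
#' implementations differ in how the period of interest (POI, the wettest/
#' driest/warmest/coldest month or quarter) is selected, how monthly
#' temperature extremes are summarized, where mean temperature comes from,
#' and how quarters crossing the December/January boundary are built.
#' `scheme_config()` makes every one of those switches explicit so a result
#' always carries the full recipe that produced it.
#'
#' @param poi_scheme `"CLIM"` selects each POI once from the whole-period
#'   monthly climatology and then averages that fixed calendar period over
#'   all years; `"BIO"` selects the POI separately within each year,
#'   evaluates it there, and averages the per-year values.
#' @param extreme_scheme for BIO5/BIO6: `"mean"` uses the monthly mean of
#'   daily maxima/minima, `"absolute"` the single most extreme daily value
#'   of the month (requires daily-derived monthly absolute extremes).
#' @param mean_temp_source `"direct"` uses the dataset's mean temperature;
#'   `"from_minmax"` computes `(tmin + tmax) / 2` at the series' native
#'   resolution (the convention of climatology databases that only
#'   distribute extreme temperatures).
#' @param quarter_convention `"consecutive_median"` labels a quarter by its
#'   middle month and takes members from the physically adjacent years at
#'   the boundary; `"same_year_wrap"` wraps within the calendar year.
#' @param edge_policy how quarters needing months outside series coverage
#'   are handled: `"drop-edge-year"` (default) drops affected years from
#'   year-by-year averaging, `"extend"` requires the extra months to be
#'   present, `"strict-missing"` marks affected quarters missing.
#' @param completeness_threshold fraction of days a month needs to count as
#'   complete during daily aggregation (default 0.8).
#' @param period integer `c(start_year, end_year)` or `NULL` for the full
#'   series coverage.
#' @param bio4_sd `"sample"` (n-1 denominator, default) or `"population"`
#'   for the standard deviation inside temperature seasonality (BIO4).
#' @param bio15_offset logical; add 1 mm to the mean in the denominator of
#'   precipitation seasonality (BIO15) so all-dry cells stay finite
#'   (default `TRUE`).
#' @return an object of class `scheme_config`.
#' @export
scheme_config <- function(poi_scheme = c("CLIM", "BIO"),
                          extreme_scheme = c("mean", "absolute"),
                          mean_temp_source = c("direct", "from_minmax"),
                          quarter_convention = c("consecutive_median",
                                                 "same_year_wrap"),
                          edge_policy = c("drop-edge-year", "extend",
                                          "strict-missing"),
                          completeness_threshold = 0.8,
                          period = NULL,
                          bio4_sd = c("sample", "population"),
                          bio15_offset = TRUE) {
  cfg <- structure(
    list(poi_scheme = match.arg(poi_scheme),
         extreme_scheme = match.arg(extreme_scheme),
         mean_temp_source = match.arg(mean_temp_source),
         quarter_convention = match.arg(quarter_convention),
         tie_break = "earliest-calendar-month",
         edge_policy = match.arg(edge_policy),
         completeness_threshold = completeness_threshold,
         period = if (!is.null(period)) as.integer(period),
         bio4_sd = match.arg(bio4_sd),
         bio15_offset = isTRUE(bio15_offset)),
    class = "scheme_config")
  if (cfg$completeness_threshold <= 0 || cfg$completeness_threshold > 1) {
    stop("completeness_threshold must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(cfg$period)) {
    if (length(cfg$period) != 2L || cfg$period[1L] > cfg$period[2L]) {
      stop("period must be c(start_year, end_year) with start <= end",
           call. = FALSE)
    }
  }
  cfg
}

#' @export
print.scheme_config <- function(x, ...) {
  cat("<scheme_config>\n")
  cat(sprintf("  POI scheme:          %s\n", x$poi_scheme))
  cat(sprintf("  extreme scheme:      %s\n", x$extreme_scheme))
  cat(sprintf("  mean temp source:    %s\n", x$mean_temp_source))
  cat(sprintf("  quarter convention:  %s\n", x$quarter_convention))
  cat(sprintf("  edge policy:         %s\n", x$edge_policy))
  cat(sprintf("  completeness:        %.2f\n", x$completeness_threshold))
  cat(sprintf("  period:              %s\n",
              if (is.null(x$period)) "full series"
              else paste(x$period, collapse = "-")))
  invisible(x)
}
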