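#' Taylor statistics of a field against a reference
#'
#' The three numbers summarized by a Taylor diagram: the field's standard
#' deviation normalized by the reference SD, the centered (mean-removed)
#' RMSE normalized by the reference SD, and the Pearson correlation, all
#' computed across masked, pairwise-complete grid boxes. The triple obeys
#' the law-of-cosines identity
#' `crmse^2 = nsd^2 + 1 - 2 * nsd * r`.
#'
#' @param field,reference numeric matrices `[lat, lon]` on the same grid.
#' @param mask optional logical matrix restricting the statistic.
#' @return object of class `taylor_stats`: `normalized_sd`,
#'   `centered_rmse`, `correlation`, `n`.
#' @export
taylor_statistics <- function(field, reference, mask = NULL) {
  if (!all(dim(field) == dim(reference))) {
    stop("field and reference are on different grids", call. = FALSE)
  }
  use <- !is.na(field) & !is.na(reference)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(field)))
    use <- use & mask
  }
  f <- field[use]; r <- reference[use]
  n <- length(f)
  if (n < 2L) stop("need at least 2 pairwise-complete boxes", call. = FALSE)
  sd_r <- stats::sd(r)
  if (!is.finite(sd_r) || sd_r == 0) {
    stop("degenerate reference: zero variance over the mask", call. = FALSE)
  }
  sd_f <- stats::sd(f)
  nsd <- sd_f / sd_r
  crmse <- sqrt(sum(((f - mean(f)) - (r - mean(r)))^2) / (n - 1)) / sd_r
  rho <- stats::cor(f, r)
  structure(list(normalized_sd = nsd, centered_rmse = crmse,
                 correlation = rho, n = n),
            class = "taylor_stats")
}

#' @export
print.taylor_stats <- function(x, ...) {
  cat(sprintf(
    "<taylor_stats> nSD %.4f  cRMSE %.4f  r %.4f  (n = %d)\n",
    x$normalized_sd, x$centered_rmse, x$correlation, x$n))
  invisible(x)
}

#' Per-gridbox difference map with summary
#'
#' `field - reference` per grid box (dataset-minus-reference sign
#' convention) plus a summary over the mask: mean, min, max, quartiles,
#' and a 1.5 x IQR-trimmed mean alongside the raw one.
#'
#' @inheritParams taylor_statistics
#' @return list with `difference` (matrix) and `summary` (named list).
#' @export
difference_map <- function(field, reference, mask = NULL) {
  if (!all(dim(field) == dim(reference))) {
    stop("field and reference are on different grids", call. = FALSE)
  }
  d <- field - reference
  use <- !is.na(d)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(d)))
    use <- use & mask
  }
  v <- d[use]
  if (!length(v)) {
    return(list(difference = d, summary = list(n = 0L)))
  }
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3L] - q[1L]
  inlier <- v >= q[1L] - 1.5 * iqr & v <= q[3L] + 1.5 * iqr
  list(difference = d,
       summary = list(n = length(v), mean = mean(v),
                      mean_trimmed = mean(v[inlier]),
                      min = min(v), q25 = q[1L], median = q[2L],
                      q75 = q[3L], max = max(v)))
}

#' Per-gridbox agreement of two daily series
#'
#' For each grid box: the standard deviation of the difference of the two
#' daily series and their Pearson correlation, over pairwise-complete
#' days.
#'
#' @param seriesA,seriesB daily [climate_grid()]s on the same grid and
#'   time axis.
#' @param variable which variable to compare (default `"tmean"`).
#' @return list of matrices `sd_diff` and `correlation`.
#' @export
daily_series_agreement <- function(seriesA, seriesB, variable = "tmean") {
  stopifnot(inherits(seriesA, "climate_grid"),
            inherits(seriesB, "climate_grid"))
  if (seriesA$step != "daily" || seriesB$step != "daily") {
    stop("both series must be daily", call. = FALSE)
  }
  if (length(seriesA$time) != length(seriesB$time) ||
      any(seriesA$time != seriesB$time)) {
    stop("time axes differ", call. = FALSE)
  }
  if (!isTRUE(all.equal(seriesA$lon, seriesB$lon)) ||
      !isTRUE(all.equal(seriesA$lat, seriesB$lat))) {
    stop("grids differ", call. = FALSE)
  }
  a <- seriesA[[variable]]; b <- seriesB[[variable]]
  if (is.null(a) || is.null(b)) {
    stop(sprintf("variable '%s' absent from one of the series", variable),
         call. = FALSE)
  }
  nla <- length(seriesA$lat); nlo <- length(seriesA$lon)
  ma <- as_ts_matrix(a); mb <- as_ts_matrix(b)
  ns <- ncol(ma)
  sd_diff <- corr <- rep(NA_real_, ns)
  for (j in seq_len(ns)) {
    ok <- !is.na(ma[, j]) & !is.na(mb[, j])
    if (sum(ok) >= 2L) {
      sd_diff[j] <- stats::sd(ma[ok, j] - mb[ok, j])
      sa <- stats::sd(ma[ok, j]); sb <- stats::sd(mb[ok, j])
      if (sa > 0 && sb > 0) corr[j] <- stats::cor(ma[ok, j], mb[ok, j])
    }
  }
  list(sd_diff = matrix(sd_diff, nla, nlo),
       correlation = matrix(corr, nla, nlo))
}

#' Taylor statistics for a full 19-variable suite
#'
#' One [taylor_statistics()] row per bioclimatic variable, comparing a
#' computed result against a reference result on the same grid. Variables
#' with a degenerate (zero-variance or all-missing) reference are flagged
#' and left `NA`; the others proceed.
#'
#' @param resultA,reference `bcv_result`s on the same grid.
#' @param mask optional logical matrix `[lat, lon]`; defaults to the
#'   reference land mask.
#' @return data.frame with columns `variable`, `normalized_sd`,
#'   `centered_rmse`, `correlation`, `n`, `flag`.
#' @export
bcv_suite_comparison <- function(resultA, reference, mask = NULL) {
  stopifnot(inherits(resultA, "bcv_result"),
            inherits(reference, "bcv_result"))
  if (!isTRUE(all.equal(resultA$lon, reference$lon)) ||
      !isTRUE(all.equal(resultA$lat, reference$lat))) {
    stop("results are on different grids", call. = FALSE)
  }
  if (is.null(mask)) mask <- reference$land_mask
  rows <- lapply(paste0("bio", 1:19), function(nm) {
    fa <- resultA$values[[nm]]; fr <- reference$values[[nm]]
    ts <- tryCatch(taylor_statistics(fa, fr, mask), error = function(e) e)
    if (inherits(ts, "error")) {
      data.frame(variable = nm, normalized_sd = NA_real_,
                 centered_rmse = NA_real_, correlation = NA_real_,
                 n = NA_integer_, flag = conditionMessage(ts),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(variable = nm, normalized_sd = ts$normalized_sd,
                 centered_rmse = ts$centered_rmse,
                 correlation = ts$correlation, n = ts$n, flag = "",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
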