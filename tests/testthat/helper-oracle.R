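# Independent brute-force oracle: straight-line per-gridbox loops,
# sharing no code with the package engine. Monthly input, mean extreme
# scheme, direct mean-temperature source.

oracle_box_series <- function(series, v, i, j, years) {
  # [12, nyears] matrix of monthly values for one box
  yr <- as.POSIXlt(series$time)$year + 1900
  mo <- as.POSIXlt(series$time)$mon + 1
  out <- matrix(NA_real_, 12, length(years))
  for (t in seq_along(series$time)) {
    y <- match(yr[t], years)
    if (!is.na(y)) out[mo[t], y] <- series[[v]][t, i, j]
  }
  out
}

# value of month m of year y, looking outside `years` if the series has it
oracle_month_value <- function(series, v, i, j, year, month) {
  yr <- as.POSIXlt(series$time)$year + 1900
  mo <- as.POSIXlt(series$time)$mon + 1
  t <- which(yr == year & mo == month)
  if (!length(t)) return(NULL)
  series[[v]][t[1], i, j]
}

oracle_clim <- function(m12xY) {
  sapply(1:12, function(m) {
    v <- m12xY[m, ]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  })
}

oracle_argext <- function(v, direction) {
  if (all(is.na(v))) return(NA_integer_)
  if (direction == "max") which.max(v) else which.min(v)
}

# quarter members for center c of year y (consecutive months, median label)
oracle_quarter_members <- function(center, year) {
  mons <- center + c(-1, 0, 1)
  yrs <- rep(year, 3)
  yrs[mons < 1] <- year - 1
  yrs[mons > 12] <- year + 1
  mons <- ((mons - 1) %% 12) + 1
  cbind(year = yrs, month = mons)
}

# all BCVs + selections for one gridbox; scheme in c("CLIM", "BIO")
oracle_box_bcvs <- function(series, i, j, years, scheme) {
  tmean <- oracle_box_series(series, "tmean", i, j, years)
  tmin <- oracle_box_series(series, "tmin", i, j, years)
  tmax <- oracle_box_series(series, "tmax", i, j, years)
  prec <- oracle_box_series(series, "precip", i, j, years)
  cl_t <- oracle_clim(tmean); cl_n <- oracle_clim(tmin)
  cl_x <- oracle_clim(tmax); cl_p <- oracle_clim(prec)
  nY <- length(years)

  month_stat <- function(mat, cl, direction) {
    if (scheme == "CLIM") {
      m <- oracle_argext(cl, direction)
      list(value = cl[m], month = m)
    } else {
      vals <- months <- rep(NA_real_, nY)
      for (y in 1:nY) {
        m <- oracle_argext(mat[, y], direction)
        if (!is.na(m)) { months[y] <- m; vals[y] <- mat[m, y] }
      }
      tab <- table(factor(months, levels = 1:12))
      modal <- if (sum(tab) == 0) NA_integer_ else which.max(tab)
      list(value = mean(vals, na.rm = TRUE), month = modal,
           per_year = months)
    }
  }

  # quarter statistics: evaluate all 12 centers, every year
  qt <- qp <- matrix(NA_real_, 12, nY)
  usable <- rep(TRUE, nY)
  for (y in 1:nY) {
    for (cc in 1:12) {
      mem <- oracle_quarter_members(cc, years[y])
      tv <- pv <- numeric(0)
      for (k in 1:3) {
        a <- oracle_month_value(series, "tmean", i, j,
                                mem[k, 1], mem[k, 2])
        b <- oracle_month_value(series, "precip", i, j,
                                mem[k, 1], mem[k, 2])
        if (is.null(a) || is.null(b)) { usable[y] <- FALSE; break }
        tv <- c(tv, a); pv <- c(pv, b)
      }
      if (length(tv) == 3) {
        qt[cc, y] <- mean(tv)
        qp[cc, y] <- sum(pv)
      }
    }
  }
  qt[, !usable] <- NA; qp[, !usable] <- NA
  qt_cl <- sapply(1:12, function(cc) {
    mons <- ((cc + c(-1, 0, 1) - 1) %% 12) + 1
    mean(cl_t[mons])
  })
  qp_cl <- sapply(1:12, function(cc) {
    mons <- ((cc + c(-1, 0, 1) - 1) %% 12) + 1
    sum(cl_p[mons])
  })

  quarter_stat <- function(sel_mat, sel_cl, val_mat, val_cl, direction) {
    if (scheme == "CLIM") {
      cc <- oracle_argext(sel_cl, direction)
      list(value = val_cl[cc], center = cc)
    } else {
      vals <- centers <- rep(NA_real_, nY)
      for (y in 1:nY) {
        cc <- oracle_argext(sel_mat[, y], direction)
        if (!is.na(cc)) { centers[y] <- cc; vals[y] <- val_mat[cc, y] }
      }
      tab <- table(factor(centers, levels = 1:12))
      modal <- if (sum(tab) == 0) NA_integer_ else which.max(tab)
      list(value = mean(vals, na.rm = TRUE), center = modal,
           per_year = centers)
    }
  }

  b5 <- month_stat(tmax, cl_x, "max")
  b6 <- month_stat(tmin, cl_n, "min")
  b13 <- month_stat(prec, cl_p, "max")
  b14 <- month_stat(prec, cl_p, "min")
  wet <- quarter_stat(qp, qp_cl, qp, qp_cl, "max")
  dry <- quarter_stat(qp, qp_cl, qp, qp_cl, "min")
  hot <- quarter_stat(qt, qt_cl, qt, qt_cl, "max")
  cold <- quarter_stat(qt, qt_cl, qt, qt_cl, "min")
  wet_t <- quarter_stat(qp, qp_cl, qt, qt_cl, "max")
  dry_t <- quarter_stat(qp, qp_cl, qt, qt_cl, "min")
  hot_p <- quarter_stat(qt, qt_cl, qp, qp_cl, "max")
  cold_p <- quarter_stat(qt, qt_cl, qp, qp_cl, "min")

  bio5 <- b5$value; bio6 <- b6$value
  bio2 <- mean(cl_x - cl_n)
  bio7 <- bio5 - bio6
  list(
    bio1 = mean(cl_t), bio2 = bio2,
    bio3 = if (!is.na(bio7) && bio7 > 0) 100 * bio2 / bio7 else NA_real_,
    bio4 = 100 * sd(cl_t), bio5 = bio5, bio6 = bio6, bio7 = bio7,
    bio8 = wet_t$value, bio9 = dry_t$value,
    bio10 = hot$value, bio11 = cold$value,
    bio12 = sum(cl_p), bio13 = b13$value, bio14 = b14$value,
    bio15 = 100 * sd(cl_p) / (mean(cl_p) + 1),
    bio16 = wet$value, bio17 = dry$value,
    bio18 = hot_p$value, bio19 = cold_p$value,
    sel = list(warmest_month = b5$month, coldest_month = b6$month,
               wettest_month = b13$month, driest_month = b14$month,
               wettest_quarter = wet$center, driest_quarter = dry$center,
               warmest_quarter = hot$center, coldest_quarter = cold$center))
}

oracle_all_bcvs <- function(series, scheme,
                            years = range(as.POSIXlt(series$time)$year) +
                              1900) {
  years <- years[1]:years[2]
  nla <- length(series$lat); nlo <- length(series$lon)
  vals <- lapply(1:19, function(k) matrix(NA_real_, nla, nlo))
  names(vals) <- paste0("bio", 1:19)
  sels <- list()
  for (nm in c("warmest_month", "coldest_month", "wettest_month",
               "driest_month", "wettest_quarter", "driest_quarter",
               "warmest_quarter", "coldest_quarter")) {
    sels[[nm]] <- matrix(NA_integer_, nla, nlo)
  }
  for (i in 1:nla) for (j in 1:nlo) {
    b <- oracle_box_bcvs(series, i, j, years, scheme)
    for (k in 1:19) vals[[k]][i, j] <- b[[paste0("bio", k)]]
    for (nm in names(sels)) sels[[nm]][i, j] <- b$sel[[nm]]
  }
  list(values = vals, selections = sels)
}
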