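#' @title CF NetCDF input/output
#' @description bcvcalc reads and writes NetCDF-3 classic (CDF-1) files
#'   with CF-style metadata through a small self-contained codec: named
#'   dimensions, global and per-variable attributes, and fixed-size
#'   variables of type char/short/int/float/double. This covers the
#'   CF-convention lon/lat/time grids the package exchanges. 64-bit-offset
#'   and NetCDF-4/HDF5 files are rejected with a clear message.
#' @name netcdf-io
#' @keywords internal
NULL

nc_type_code <- c(byte = 1L, char = 2L, short = 3L, int = 4L,
                  float = 5L, double = 6L)
nc_type_size <- c(1L, 1L, 2L, 4L, 4L, 8L)

nc_pad <- function(n) (4L - n %% 4L) %% 4L

# ---- writer ---------------------------------------------------------------

nc_att_type <- function(v) {
  if (is.character(v)) "char" else if (is.integer(v)) "int" else "double"
}

nc_write_name <- function(con, name) {
  b <- charToRaw(name)
  writeBin(length(b), con, size = 4L, endian = "big")
  writeBin(b, con)
  if (nc_pad(length(b))) writeBin(raw(nc_pad(length(b))), con)
}

nc_write_att_block <- function(con, atts) {
  if (!length(atts)) {
    writeBin(c(0L, 0L), con, size = 4L, endian = "big")
    return(invisible())
  }
  writeBin(c(12L, length(atts)), con, size = 4L, endian = "big")
  for (nm in names(atts)) {
    v <- atts[[nm]]
    ty <- nc_att_type(v)
    nc_write_name(con, nm)
    writeBin(nc_type_code[[ty]], con, size = 4L, endian = "big")
    if (ty == "char") {
      b <- charToRaw(v)
      writeBin(length(b), con, size = 4L, endian = "big")
      writeBin(b, con)
      if (nc_pad(length(b))) writeBin(raw(nc_pad(length(b))), con)
    } else if (ty == "int") {
      writeBin(length(v), con, size = 4L, endian = "big")
      writeBin(as.integer(v), con, size = 4L, endian = "big")
    } else {
      writeBin(length(v), con, size = 4L, endian = "big")
      writeBin(as.double(v), con, size = 8L, endian = "big")
    }
  }
}

nc_var_size <- function(var, dims) {
  n <- prod(vapply(var$dims, function(i) dims[[i]]$len, numeric(1)))
  sz <- n * nc_type_size[nc_type_code[[var$type]]]
  as.integer(sz + nc_pad(sz))
}

nc_serialize_header <- function(dims, gatts, vars, begins) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x43, 0x44, 0x46, 0x01)), con)
  writeBin(0L, con, size = 4L, endian = "big")          # numrecs
  if (length(dims)) {
    writeBin(c(10L, length(dims)), con, size = 4L, endian = "big")
    for (d in dims) {
      nc_write_name(con, d$name)
      writeBin(as.integer(d$len), con, size = 4L, endian = "big")
    }
  } else writeBin(c(0L, 0L), con, size = 4L, endian = "big")
  nc_write_att_block(con, gatts)
  if (length(vars)) {
    writeBin(c(11L, length(vars)), con, size = 4L, endian = "big")
    for (i in seq_along(vars)) {
      v <- vars[[i]]
      nc_write_name(con, v$name)
      writeBin(length(v$dims), con, size = 4L, endian = "big")
      if (length(v$dims)) {
        writeBin(as.integer(v$dims) - 1L, con, size = 4L, endian = "big")
      }
      nc_write_att_block(con, v$atts)
      writeBin(nc_type_code[[v$type]], con, size = 4L, endian = "big")
      writeBin(nc_var_size(v, dims), con, size = 4L, endian = "big")
      writeBin(as.integer(begins[i]), con, size = 4L, endian = "big")
    }
  } else writeBin(c(0L, 0L), con, size = 4L, endian = "big")
  rawConnectionValue(con)
}

# dims: list(list(name, len)); gatts: named list; vars: list(list(name,
# dims = 1-based dim indices, atts, type, data = vector in row-major
# order of the variable's dims))
write_netcdf3 <- function(path, dims, gatts, vars) {
  vsizes <- vapply(vars, nc_var_size, integer(1), dims = dims)
  h0 <- nc_serialize_header(dims, gatts, vars, rep(0L, length(vars)))
  begins <- length(h0) + c(0L, cumsum(vsizes))[seq_along(vars)]
  header <- nc_serialize_header(dims, gatts, vars, begins)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  for (v in vars) {
    ty <- v$type
    if (ty == "char") {
      b <- charToRaw(paste(v$data, collapse = ""))
      writeBin(b, con)
      if (nc_pad(length(b))) writeBin(raw(nc_pad(length(b))), con)
    } else if (ty %in% c("int", "short")) {
      sz <- if (ty == "int") 4L else 2L
      writeBin(as.integer(v$data), con, size = sz, endian = "big")
      n <- length(v$data) * sz
      if (nc_pad(n)) writeBin(raw(nc_pad(n)), con)
    } else {
      sz <- if (ty == "double") 8L else 4L
      writeBin(as.double(v$data), con, size = sz, endian = "big")
      n <- length(v$data) * sz
      if (nc_pad(n)) writeBin(raw(nc_pad(n)), con)
    }
  }
  invisible(path)
}

# ---- reader ---------------------------------------------------------------

read_netcdf3 <- function(path) {
  r <- readBin(path, raw(), n = file.size(path))
  if (length(r) < 8L) stop("not a NetCDF file: ", path, call. = FALSE)
  if (rawToChar(r[1:3]) != "CDF") {
    stop(path, " is not NetCDF classic; NetCDF-4/HDF5 is not supported ",
         "by this reader (convert with `nccopy -k classic`)",
         call. = FALSE)
  }
  if (as.integer(r[4L]) != 1L) {
    stop(path, " uses the 64-bit-offset or CDF-5 variant; only CDF-1 ",
         "classic files are supported", call. = FALSE)
  }
  pos <- 5L
  rd_int <- function(n = 1L) {
    out <- readBin(r[pos:(pos + 4L * n - 1L)], integer(), n = n,
                   size = 4L, endian = "big")
    pos <<- pos + 4L * n
    out
  }
  rd_name <- function() {
    len <- rd_int()
    nm <- rawToChar(r[pos:(pos + len - 1L)])
    pos <<- pos + len + nc_pad(len)
    nm
  }
  rd_values <- function(type, n) {
    sz <- nc_type_size[type]
    nb <- sz * n
    bytes <- r[pos:(pos + nb - 1L)]
    pos <<- pos + nb + nc_pad(nb)
    switch(as.character(type),
           "1" = as.integer(bytes),
           "2" = rawToChar(bytes),
           "3" = readBin(bytes, integer(), n = n, size = 2L,
                         endian = "big"),
           "4" = readBin(bytes, integer(), n = n, size = 4L,
                         endian = "big"),
           "5" = readBin(bytes, double(), n = n, size = 4L,
                         endian = "big"),
           "6" = readBin(bytes, double(), n = n, size = 8L,
                         endian = "big"))
  }
  rd_atts <- function() {
    tag <- rd_int(); n <- rd_int()
    if (tag == 0L || n == 0L) return(list())
    atts <- list()
    for (i in seq_len(n)) {
      nm <- rd_name()
      ty <- rd_int()
      ne <- rd_int()
      atts[[nm]] <- rd_values(ty, ne)
    }
    atts
  }
  numrecs <- rd_int()
  tag <- rd_int(); ndims <- rd_int()
  dims <- list()
  if (tag == 10L) {
    for (i in seq_len(ndims)) {
      dims[[i]] <- list(name = rd_name(), len = rd_int())
    }
  }
  gatts <- rd_atts()
  tag <- rd_int(); nvars <- rd_int()
  vars <- list()
  if (tag == 11L) {
    for (i in seq_len(nvars)) {
      nm <- rd_name()
      nd <- rd_int()
      dimids <- if (nd) rd_int(nd) + 1L else integer(0)
      atts <- rd_atts()
      ty <- rd_int()
      vsize <- rd_int()
      begin <- rd_int()
      vars[[nm]] <- list(name = nm, dims = dimids, atts = atts,
                         type = ty, begin = begin)
    }
  }
  for (nm in names(vars)) {
    v <- vars[[nm]]
    lens <- vapply(v$dims, function(i) dims[[i]]$len, numeric(1))
    if (any(lens == 0L)) {
      stop("record (unlimited-dimension) variables are not supported: ",
           nm, call. = FALSE)
    }
    pos <- v$begin + 1L
    vars[[nm]]$data <- rd_values(v$type, as.integer(prod(c(1, lens))))
    vars[[nm]]$dimlens <- as.integer(lens)
    vars[[nm]]$dimnames <- vapply(v$dims, function(i) dims[[i]]$name, "")
  }
  list(dims = dims, gatts = gatts, vars = vars)
}

# ---- climate_grid <-> CF file --------------------------------------------

#' Write a climate grid as CF NetCDF
#'
#' Writes a NetCDF-3 classic file with lon/lat/time coordinate variables,
#' CF units (`degrees_east`, `degrees_north`, `days since 1970-01-01`,
#' `degC`, `mm`), a `proleptic_gregorian` calendar and NaN `_FillValue`s.
#' Values round-trip bit-identically through [read_cf_grid()].
#'
#' @param series a [climate_grid()].
#' @param path output file path.
#' @param title optional title attribute.
#' @return `path`, invisibly.
#' @export
write_cf_grid <- function(series, path, title = "bcvcalc climate grid") {
  stopifnot(inherits(series, "climate_grid"))
  nlo <- length(series$lon); nla <- length(series$lat)
  nt <- length(series$time)
  dims <- list(list(name = "time", len = nt),
               list(name = "lat", len = nla),
               list(name = "lon", len = nlo))
  std <- list(
    tmin = c("air_temperature", "degC",
             "daily minimum 2m temperature"),
    tmax = c("air_temperature", "degC",
             "daily maximum 2m temperature"),
    tmean = c("air_temperature", "degC", "mean 2m temperature"),
    precip = c("precipitation_amount", "mm", "precipitation total"),
    tmax_abs = c("air_temperature", "degC",
                 "monthly absolute daily maximum temperature"),
    tmin_abs = c("air_temperature", "degC",
                 "monthly absolute daily minimum temperature"))
  vars <- list(
    list(name = "time", dims = 1L, type = "double",
         atts = list(units = "days since 1970-01-01",
                     calendar = "proleptic_gregorian",
                     standard_name = "time"),
         data = as.double(series$time)),
    list(name = "lat", dims = 2L, type = "double",
         atts = list(units = "degrees_north", standard_name = "latitude"),
         data = series$lat),
    list(name = "lon", dims = 3L, type = "double",
         atts = list(units = "degrees_east", standard_name = "longitude"),
         data = series$lon))
  for (v in grid_vars(series)) {
    vars[[length(vars) + 1L]] <- list(
      name = v, dims = c(1L, 2L, 3L), type = "double",
      atts = list(units = std[[v]][2L], standard_name = std[[v]][1L],
                  long_name = std[[v]][3L], `_FillValue` = NaN),
      data = as.vector(aperm(series[[v]], c(3L, 2L, 1L))))
  }
  vars[[length(vars) + 1L]] <- list(
    name = "land_mask", dims = c(2L, 3L), type = "int",
    atts = list(long_name = "land mask (1 = land)"),
    data = as.integer(t(series$land_mask)))
  gatts <- list(Conventions = "CF-1.8", title = title,
                source = "bcvcalc", time_step = series$step)
  write_netcdf3(path, dims, gatts, vars)
  invisible(path)
}

cf_default_mapping <- list(
  tmin = c("tmin", "tasmin", "tn", "tmn"),
  tmax = c("tmax", "tasmax", "tx", "tmx"),
  tmean = c("tmean", "tas", "t2m", "tg", "tavg"),
  precip = c("precip", "pr", "tp", "rr", "pre", "precipitation"),
  tmax_abs = "tmax_abs", tmin_abs = "tmin_abs")

cf_parse_time <- function(values, atts) {
  units <- atts$units
  if (is.null(units)) stop("time variable has no units", call. = FALSE)
  cal <- atts$calendar
  if (!is.null(cal) &&
      !tolower(cal) %in% c("standard", "gregorian",
                           "proleptic_gregorian")) {
    stop("unsupported calendar '", cal,
         "'; only standard/proleptic Gregorian is handled", call. = FALSE)
  }
  m <- regmatches(units,
                  regexec("^(days|hours|minutes|seconds)\\s+since\\s+([0-9]{1,4}-[0-9]{1,2}-[0-9]{1,2})",
                          units))[[1L]]
  if (!length(m)) {
    stop("cannot parse time units '", units, "'", call. = FALSE)
  }
  fac <- switch(m[2L], days = 1, hours = 24, minutes = 1440,
                seconds = 86400)
  as.Date(m[3L]) + round(values / fac)
}

cf_convert_units <- function(x, units, kind) {
  if (is.null(units)) return(x)
  u <- gsub("\\s+", " ", trimws(tolower(units)))
  if (kind == "temp") {
    if (u %in% c("k", "kelvin")) return(x - 273.15)
    if (u %in% c("degc", "celsius", "deg_c", "degrees celsius", "c",
                 "degree_celsius", "degrees_c")) return(x)
    stop("unmappable temperature units '", units, "'", call. = FALSE)
  }
  if (u %in% c("m", "m of water equivalent", "meters")) return(x * 1000)
  if (u %in% c("mm", "kg m-2", "kg/m^2", "kg m**-2", "millimeters")) {
    return(x)
  }
  stop("unmappable precipitation units '", units, "'", call. = FALSE)
}

#' Read a CF NetCDF grid
#'
#' Reads a NetCDF-3 classic file into a [climate_grid()]: coordinates are
#' located by standard names (`lon`/`longitude`, `lat`/`latitude`,
#' `time`), CF time units are decoded (standard calendars only),
#' temperatures are converted to degrees C (from Kelvin where declared)
#' and precipitation to mm (from m), descending latitudes are reordered
#' ascending, and fill values become `NA`.
#'
#' @param path NetCDF file.
#' @param mapping optional named character vector mapping canonical names
#'   (`tmin`, `tmax`, `tmean`, `precip`, `tmax_abs`, `tmin_abs`) to the
#'   file's variable names, e.g. `c(tmean = "t2m", precip = "tp")`.
#' @param nodata optional numeric nodata value to treat as missing, in
#'   addition to any declared `_FillValue`/`missing_value`.
#' @return a [climate_grid()].
#' @export
read_cf_grid <- function(path, mapping = NULL, nodata = NULL) {
  nc <- read_netcdf3(path)
  dnames <- tolower(vapply(nc$dims, `[[`, "", "name"))
  find_coord <- function(cands, what) {
    i <- which(dnames %in% cands)
    if (!length(i)) {
      stop("no ", what, " coordinate found in ", path, call. = FALSE)
    }
    nm <- nc$dims[[i[1L]]]$name
    if (is.null(nc$vars[[nm]])) {
      stop(what, " dimension '", nm, "' has no coordinate variable",
           call. = FALSE)
    }
    nc$vars[[nm]]
  }
  vlon <- find_coord(c("lon", "longitude", "x"), "longitude")
  vlat <- find_coord(c("lat", "latitude", "y"), "latitude")
  vtime <- find_coord(c("time", "t"), "time")
  lon <- as.double(vlon$data)
  lat <- as.double(vlat$data)
  time <- cf_parse_time(as.double(vtime$data), vtime$atts)

  resolve <- function(canon) {
    if (!is.null(mapping) && canon %in% names(mapping)) {
      if (!mapping[[canon]] %in% names(nc$vars)) {
        stop("mapped variable '", mapping[[canon]], "' (", canon,
             ") not found in ", path, call. = FALSE)
      }
      return(mapping[[canon]])
    }
    hits <- intersect(cf_default_mapping[[canon]], names(nc$vars))
    if (length(hits)) hits[1L] else NULL
  }
  fields <- list()
  for (canon in names(cf_default_mapping)) {
    src <- resolve(canon)
    if (is.null(src)) next
    v <- nc$vars[[src]]
    dn <- tolower(v$dimnames)
    it <- which(dn %in% c("time", "t"))
    ila <- which(dn %in% c("lat", "latitude", "y"))
    ilo <- which(dn %in% c("lon", "longitude", "x"))
    if (length(it) != 1L || length(ila) != 1L || length(ilo) != 1L) {
      stop("variable '", src, "' is not on (time, lat, lon) dimensions",
           call. = FALSE)
    }
    # file data is row-major over v$dims; build column-major then permute
    arr <- array(as.double(v$data), dim = rev(v$dimlens))
    arr <- aperm(arr, rev(seq_along(v$dimlens)))   # now in v$dims order
    arr <- aperm(arr, order(c(it, ila, ilo)))      # -> [time, lat, lon]
    fills <- c(v$atts[["_FillValue"]], v$atts[["missing_value"]], nodata)
    for (fv in fills) if (!is.na(fv)) arr[arr == fv] <- NA_real_
    arr[is.nan(arr)] <- NA_real_
    kind <- if (canon == "precip") "precip" else "temp"
    fields[[canon]] <- cf_convert_units(arr, v$atts$units, kind)
  }
  if (!length(fields)) {
    stop("no recognizable climate variables in ", path,
         "; pass an explicit `mapping`", call. = FALSE)
  }
  if (any(lon >= 180)) lon <- ((lon + 180) %% 360) - 180
  olo <- order(lon); ola <- order(lat)
  if (!identical(olo, seq_along(lon)) || !identical(ola, seq_along(lat))) {
    lon <- lon[olo]; lat <- lat[ola]
    fields <- lapply(fields, function(a) a[, ola, olo, drop = FALSE])
  }
  mask <- NULL
  if (!is.null(nc$vars$land_mask)) {
    lm <- nc$vars$land_mask
    mask <- matrix(as.logical(lm$data), length(lon),
                   length(lat))   # row-major (lat, lon): lon fastest
    mask <- t(mask)[ola, olo, drop = FALSE]
  }
  climate_grid(lon = lon, lat = lat, time = time,
               tmin = fields$tmin, tmax = fields$tmax,
               tmean = fields$tmean, precip = fields$precip,
               tmax_abs = fields$tmax_abs, tmin_abs = fields$tmin_abs,
               land_mask = mask,
               attrs = list(source_file = path, gatts = nc$gatts))
}
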