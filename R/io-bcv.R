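#' @title BCV raster stacks on disk
#' @description BCV results are exchanged as one raster layer per
#'   variable. Two formats are supported: a directory of ESRI ASCII grids
#'   (`bio_1.asc` ... `bio_19.asc`, the WorldClim one-file-per-variable
#'   layout in a plain-text GIS raster format) with a JSON sidecar
#'   carrying units and full scheme provenance, or a single CF NetCDF
#'   file with 19 variables.
#' @name bcv-io
#' @keywords internal
NULL

asc_nodata <- -9999

write_asc <- function(field, lon, lat, path, nodata = asc_nodata) {
  dlo <- diff(lon); dla <- diff(lat)
  cell <- mean(c(dlo, dla))
  if (length(c(dlo, dla)) &&
      any(abs(c(dlo, dla) - cell) > 1e-6 * max(abs(cell), 1))) {
    stop("ESRI ASCII grids need equal square cell sizes; ",
         "use the NetCDF format for this grid", call. = FALSE)
  }
  if (!length(dlo) && !length(dla)) cell <- 1
  v <- field
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", length(lon)),
               sprintf("nrows %d", length(lat)),
               sprintf("xllcorner %.10g", min(lon) - cell / 2),
               sprintf("yllcorner %.10g", min(lat) - cell / 2),
               sprintf("cellsize %.10g", cell),
               sprintf("NODATA_value %g", nodata)), con)
  for (i in rev(seq_along(lat))) {          # north to south
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  }
  invisible(path)
}

read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop(path, " is not an ESRI ASCII grid", call. = FALSE)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- hdr$ncols; nr <- hdr$nrows
  if (length(vals) != nc * nr) {
    stop(path, ": expected ", nc * nr, " values, found ", length(vals),
         call. = FALSE)
  }
  m <- matrix(vals, nr, nc, byrow = TRUE)[nr:1, , drop = FALSE]
  nd <- hdr$nodata_value
  if (!is.null(nd)) m[m == nd] <- NA_real_
  lon <- hdr$xllcorner + hdr$cellsize * (seq_len(nc) - 0.5)
  lat <- hdr$yllcorner + hdr$cellsize * (seq_len(nr) - 0.5)
  list(field = m, lon = lon, lat = lat)
}

#' Write a BCV result to disk
#'
#' Writes one raster layer per bioclimatic variable in deterministic
#' order BIO1...BIO19, with units and the full calculation-scheme
#' provenance embedded as metadata. On failure, partial outputs are
#' removed.
#'
#' @param result a `bcv_result`.
#' @param path output directory (`format = "asc"`) or `.nc` file path
#'   (`format = "netcdf"`).
#' @param format `"asc"` (ESRI ASCII grid per variable + JSON sidecar) or
#'   `"netcdf"` (single CF NetCDF-3 file).
#' @return `path`, invisibly.
#' @export
write_bcv <- function(result, path, format = c("asc", "netcdf")) {
  stopifnot(inherits(result, "bcv_result"))
  format <- match.arg(format)
  units <- bcv_units()
  cfg <- result$config
  prov <- list(
    poi_scheme = cfg$poi_scheme, extreme_scheme = cfg$extreme_scheme,
    mean_temp_source = cfg$mean_temp_source,
    quarter_convention = cfg$quarter_convention,
    edge_policy = cfg$edge_policy,
    completeness_threshold = cfg$completeness_threshold,
    bio4_sd = cfg$bio4_sd, bio15_offset = cfg$bio15_offset,
    period = result$period, units = as.list(units),
    provenance = result$provenance)
  if (format == "asc") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    written <- character(0)
    ok <- FALSE
    on.exit(if (!ok) unlink(written))
    for (i in 1:19) {
      f <- file.path(path, sprintf("bio_%d.asc", i))
      write_asc(result$values[[paste0("bio", i)]], result$lon,
                result$lat, f)
      written <- c(written, f)
    }
    meta <- file.path(path, "bcv_metadata.json")
    jsonlite::write_json(prov, meta, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, meta)
    ok <- TRUE
    return(invisible(path))
  }
  nla <- length(result$lat); nlo <- length(result$lon)
  dims <- list(list(name = "lat", len = nla),
               list(name = "lon", len = nlo))
  vars <- list(
    list(name = "lat", dims = 1L, type = "double",
         atts = list(units = "degrees_north", standard_name = "latitude"),
         data = result$lat),
    list(name = "lon", dims = 2L, type = "double",
         atts = list(units = "degrees_east", standard_name = "longitude"),
         data = result$lon))
  for (i in 1:19) {
    nm <- paste0("bio", i)
    vars[[length(vars) + 1L]] <- list(
      name = nm, dims = c(1L, 2L), type = "double",
      atts = list(units = unname(units[nm]), `_FillValue` = NaN),
      data = as.vector(t(result$values[[nm]])))
  }
  gatts <- list(Conventions = "CF-1.8",
                title = "bioclimatic variables BIO1-BIO19",
                source = "bcvcalc",
                scheme = jsonlite::toJSON(prov, auto_unbox = TRUE))
  ok <- FALSE
  on.exit(if (!ok) unlink(path))
  write_netcdf3(path, dims, gatts, vars)
  ok <- TRUE
  invisible(path)
}

#' Read a BCV raster stack
#'
#' Reads a stack written by [write_bcv()] (or any WorldClim-style
#' directory of per-variable rasters) back into a `bcv_result` with
#' provenance marked `external-reference`. Missing layers are allowed and
#' flagged; inconsistent grids across layers are rejected.
#'
#' @param path directory of `.asc` layers or a `.nc` file.
#' @param pattern `sprintf` pattern locating layer `i` in a directory.
#' @return a `bcv_result`.
#' @export
read_bcv_stack <- function(path, pattern = "bio_%d.asc") {
  if (dir.exists(path)) {
    lon <- lat <- NULL
    values <- list()
    failures <- list()
    for (i in 1:19) {
      nm <- paste0("bio", i)
      f <- file.path(path, sprintf(pattern, i))
      if (!file.exists(f)) {
        failures[[nm]] <- "layer file missing"
        next
      }
      a <- read_asc(f)
      if (is.null(lon)) {
        lon <- a$lon; lat <- a$lat
      } else if (length(a$lon) != length(lon) ||
                 length(a$lat) != length(lat) ||
                 max(abs(a$lon - lon)) > 1e-6 ||
                 max(abs(a$lat - lat)) > 1e-6) {
        stop("inconsistent grids across layers in ", path, call. = FALSE)
      }
      values[[nm]] <- a$field
    }
    if (is.null(lon)) stop("no BCV layers found in ", path, call. = FALSE)
    for (nm in paste0("bio", 1:19)) {
      if (is.null(values[[nm]])) {
        values[[nm]] <- matrix(NA_real_, length(lat), length(lon))
      }
    }
    values <- values[paste0("bio", 1:19)]
    meta_file <- file.path(path, "bcv_metadata.json")
    cfg <- NULL
    if (file.exists(meta_file)) {
      meta <- jsonlite::read_json(meta_file)
      cfg <- tryCatch(
        scheme_config(poi_scheme = meta$poi_scheme,
                      extreme_scheme = meta$extreme_scheme,
                      mean_temp_source = meta$mean_temp_source,
                      quarter_convention = meta$quarter_convention,
                      edge_policy = meta$edge_policy,
                      completeness_threshold =
                        meta$completeness_threshold,
                      period = unlist(meta$period),
                      bio4_sd = meta$bio4_sd,
                      bio15_offset = meta$bio15_offset),
        error = function(e) NULL)
    }
    if (is.null(cfg)) cfg <- scheme_config()
    return(structure(
      list(values = values, poi = list(), config = cfg, lon = lon,
           lat = lat, land_mask = matrix(TRUE, length(lat), length(lon)),
           period = if (!is.null(cfg$period)) cfg$period else c(NA, NA),
           failures = failures, provenance = "external-reference"),
      class = "bcv_result"))
  }
  nc <- read_netcdf3(path)
  lon <- as.double(nc$vars$lon$data)
  lat <- as.double(nc$vars$lat$data)
  values <- list()
  failures <- list()
  for (i in 1:19) {
    nm <- paste0("bio", i)
    v <- nc$vars[[nm]]
    if (is.null(v)) {
      failures[[nm]] <- "variable missing"
      values[[nm]] <- matrix(NA_real_, length(lat), length(lon))
      next
    }
    m <- matrix(as.double(v$data), length(lon), length(lat))  # lon fastest
    m <- t(m)
    m[is.nan(m)] <- NA_real_
    values[[nm]] <- m
  }
  cfg <- scheme_config()
  period <- c(NA_integer_, NA_integer_)
  if (!is.null(nc$gatts$scheme)) {
    meta <- tryCatch(jsonlite::fromJSON(nc$gatts$scheme),
                     error = function(e) NULL)
    if (!is.null(meta)) {
      cfg <- tryCatch(
        scheme_config(poi_scheme = meta$poi_scheme,
                      extreme_scheme = meta$extreme_scheme,
                      mean_temp_source = meta$mean_temp_source,
                      quarter_convention = meta$quarter_convention,
                      edge_policy = meta$edge_policy,
                      completeness_threshold =
                        meta$completeness_threshold,
                      period = meta$period, bio4_sd = meta$bio4_sd,
                      bio15_offset = meta$bio15_offset),
        error = function(e) scheme_config())
      if (!is.null(meta$period)) period <- as.integer(meta$period)
    }
  }
  structure(
    list(values = values, poi = list(), config = cfg, lon = lon,
         lat = lat, land_mask = matrix(TRUE, length(lat), length(lon)),
         period = period, failures = failures,
         provenance = "external-reference"),
    class = "bcv_result")
}
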