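#' Write a climate grid to NetCDF
#'
#' CF-style layout: dimensions `lon`, `lat`, `time`; variable `tas` in degC;
#' the elevation field, when present, as a static variable `elevation` (m).
#' Time is encoded as days since 1970-01-01 on the grid's calendar
#' (`365_day` or `proleptic_gregorian`).
#'
#' @param grid a [climate_grid].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "climate_grid"))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", grid$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", grid$lat)
  cal <- if (grid$calendar == "noleap") "365_day" else "proleptic_gregorian"
  tvals <- encode_time(grid$time, grid$calendar)
  dtime <- ncdf4::ncdim_def("time", "days since 1970-01-01", tvals,
                            unlim = TRUE, calendar = cal)
  vtas <- ncdf4::ncvar_def("tas", "degC", list(dlon, dlat, dtime),
                           missval = 1e30, prec = "double",
                           longname = "daily mean air temperature")
  vars <- list(vtas)
  if (!is.null(grid$elevation)) {
    velev <- ncdf4::ncvar_def("elevation", "m", list(dlon, dlat),
                              missval = -1, prec = "double",
                              longname = "surface elevation")
    vars <- c(vars, list(velev))
  }
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  # internal layout is [lat, lon, time]; file layout is [lon, lat, time]
  ncdf4::ncvar_put(nc, vtas, aperm(grid$tas, c(2, 1, 3)))
  if (!is.null(grid$elevation))
    ncdf4::ncvar_put(nc, "elevation", t(grid$elevation))
  ncdf4::ncatt_put(nc, 0, "provenance", grid$provenance)
  invisible(path)
}

#' Read a climate grid from NetCDF
#'
#' Expects a `tas` variable in degC or K (Kelvin is converted with a note)
#' on `lon`/`lat`/`time` dimensions; an `elevation` variable is picked up
#' when present.
#'
#' @param path NetCDF file path.
#' @return a [climate_grid].
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!"tas" %in% names(nc$var))
    stop("no 'tas' variable in ", path, "; available: ",
         paste(names(nc$var), collapse = ", "))
  units <- ncdf4::ncatt_get(nc, "tas", "units")$value
  tas <- ncdf4::ncvar_get(nc, "tas", collapse_degen = FALSE)
  if (grepl("^(K|kelvin)$", units, ignore.case = TRUE)) {
    message("converting 'tas' from Kelvin to degrees Celsius")
    tas <- tas - 273.15
  } else if (!grepl("c$|celsius", units, ignore.case = TRUE)) {
    stop(sprintf("unsupported temperature units '%s' (need degC or K)", units))
  }
  lon <- as.numeric(nc$dim$lon$vals)
  lat <- as.numeric(nc$dim$lat$vals)
  tvals <- as.numeric(nc$dim$time$vals)
  if (any(diff(tvals) <= 0)) stop("non-monotone time axis in ", path)
  cal <- ncdf4::ncatt_get(nc, "time", "calendar")$value
  calendar <- if (identical(cal, "365_day") || identical(cal, "noleap"))
    "noleap" else "gregorian"
  time <- decode_time(tvals, calendar)
  elev <- NULL
  if ("elevation" %in% names(nc$var))
    elev <- t(ncdf4::ncvar_get(nc, "elevation"))
  prov <- ncdf4::ncatt_get(nc, 0, "provenance")
  tas[tas > 1e29] <- NA
  climate_grid(lat, lon, time, aperm(tas, c(2, 1, 3)), calendar = calendar,
               elevation = elev,
               provenance = if (prov$hasatt) prov$value else "observed")
}

# days since 1970-01-01 on the grid calendar
encode_time <- function(time, calendar) {
  if (calendar == "noleap") {
    (time$year - 1970) * 365 + (time$doy - 1)
  } else {
    as.numeric(as.Date(paste0(time$year, "-01-01")) - as.Date("1970-01-01")) +
      time$doy - 1
  }
}

decode_time <- function(tvals, calendar) {
  if (calendar == "noleap") {
    year <- floor(tvals / 365) + 1970
    doy <- tvals - (year - 1970) * 365 + 1
  } else {
    d <- as.Date("1970-01-01") + tvals
    year <- as.integer(format(d, "%Y"))
    doy <- as.integer(format(d, "%j"))
  }
  data.frame(year = as.integer(year), doy = as.integer(doy))
}

#' Export one cell's series as CSV
#'
#' Long format with columns `date`, `lat`, `lon`, `temperature_c`. On the
#' noleap calendar `date` is `YYYY-DDD` (year and day-of-year).
#'
#' @param grid a [climate_grid].
#' @param lat,lon cell to export (nearest centre).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_series_csv <- function(grid, lat, lon, path) {
  years <- unique(grid$time$year)
  rows <- do.call(rbind, lapply(years, function(y) {
    s <- extract_series(grid, lat, lon, y)
    data.frame(date = sprintf("%d-%03d", y, seq_along(s$temperature)),
               lat = s$lat, lon = s$lon, temperature_c = s$temperature)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
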