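#' Gridded daily temperature container
#'
#' A `climate_grid` holds a latitude x longitude x day cube of daily mean air
#' temperature in degrees Celsius, a calendar-tagged time table, and an
#' optional companion elevation field on the same grid.
#'
#' @param lat numeric vector of cell-centre latitudes (degrees north,
#'   strictly ascending).
#' @param lon numeric vector of cell-centre longitudes (degrees east,
#'   strictly ascending).
#' @param time data frame with integer columns `year` and `doy`
#'   (day-of-year), strictly increasing in calendar order.
#' @param tas numeric array of dimension `c(length(lat), length(lon),
#'   nrow(time))`; temperature in degrees Celsius. `NA` marks masked cells.
#' @param calendar `"noleap"` (365-day model calendar) or `"gregorian"`.
#' @param elevation optional matrix `length(lat) x length(lon)` of elevation
#'   in metres.
#' @param provenance character label: `"observed"`, a member name, or
#'   `"ensemble"`.
#'
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(lat, lon, time, tas, calendar = c("noleap", "gregorian"),
                         elevation = NULL, provenance = "observed") {
  calendar <- match.arg(calendar)
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (any(is.na(lat)) || any(is.na(lon)))
    stop("coordinates must not contain missing values")
  if (length(lat) > 1 && any(diff(lat) <= 0))
    stop("'lat' must be strictly ascending")
  if (length(lon) > 1 && any(diff(lon) <= 0))
    stop("'lon' must be strictly ascending")
  if (!is.data.frame(time) || !all(c("year", "doy") %in% names(time)))
    stop("'time' must be a data frame with columns 'year' and 'doy'")
  tkey <- time$year * 1000 + time$doy
  if (any(diff(tkey) <= 0)) stop("time axis must be strictly increasing")
  if (calendar == "noleap" && any(time$doy > 365))
    stop("day-of-year > 365 is invalid on the noleap calendar")
  tas <- as.array(tas)
  expect_dim <- c(length(lat), length(lon), nrow(time))
  if (!identical(dim(tas), as.integer(expect_dim)))
    stop(sprintf("'tas' has dimension [%s]; expected [%s]",
                 paste(dim(tas), collapse = ", "),
                 paste(expect_dim, collapse = ", ")))
  if (!is.null(elevation)) {
    elevation <- as.matrix(elevation)
    if (!identical(dim(elevation), as.integer(expect_dim[1:2])))
      stop(sprintf("'elevation' has dimension [%s]; expected [%s]",
                   paste(dim(elevation), collapse = ", "),
                   paste(expect_dim[1:2], collapse = ", ")))
  }
  structure(
    list(lat = lat, lon = lon, time = time, tas = tas, calendar = calendar,
         elevation = elevation, provenance = as.character(provenance)),
    class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  yrs <- range(x$time$year)
  cat(sprintf("<climate_grid> %s, %s calendar\n", x$provenance, x$calendar))
  cat(sprintf("  %d lat x %d lon x %d days (%d-%d)\n",
              length(x$lat), length(x$lon), nrow(x$time), yrs[1], yrs[2]))
  cat(sprintf("  lat %.3f..%.3f degN, lon %.3f..%.3f degE\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  cat(sprintf("  tas: mean %.2f degC [%.2f, %.2f]%s\n",
              mean(x$tas, na.rm = TRUE), min(x$tas, na.rm = TRUE),
              max(x$tas, na.rm = TRUE),
              if (anyNA(x$tas)) " (masked cells present)" else ""))
  if (!is.null(x$elevation))
    cat(sprintf("  elevation: %.0f..%.0f m\n",
                min(x$elevation), max(x$elevation)))
  invisible(x)
}

#' @export
summary.climate_grid <- function(object, ...) {
  ann <- annual_mean_series(object)
  out <- list(provenance = object$provenance,
              n_cells = length(object$lat) * length(object$lon),
              years = range(object$time$year),
              annual_domain_mean = ann)
  class(out) <- "summary.climate_grid"
  out
}

#' @export
print.summary.climate_grid <- function(x, ...) {
  cat(sprintf("climate_grid '%s': %d cells, years %d-%d\n", x$provenance,
              x$n_cells, x$years[1], x$years[2]))
  cat("Domain-mean annual temperature (degC):\n")
  print(round(x$annual_domain_mean, 3))
  invisible(x)
}

#' Domain-mean daily temperature series
#'
#' Averages the temperature cube over all unmasked cells for each day.
#'
#' @param grid a [climate_grid].
#' @return numeric vector of length `nrow(grid$time)`.
#' @export
domain_mean_series <- function(grid) {
  stopifnot(inherits(grid, "climate_grid"))
  apply(grid$tas, 3, mean, na.rm = TRUE)
}

#' Domain-mean annual temperature
#'
#' @param grid a [climate_grid].
#' @return named numeric vector, one value per calendar year.
#' @export
annual_mean_series <- function(grid) {
  daily <- domain_mean_series(grid)
  tapply(daily, grid$time$year, mean)
}

#' Days in a calendar year
#'
#' @param year integer calendar year.
#' @param calendar `"noleap"` or `"gregorian"`.
#' @return 365, or 366 for Gregorian leap years.
#' @export
days_in_year <- function(year, calendar = "noleap") {
  if (calendar == "noleap") return(rep(365L, length(year)))
  ifelse((year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0, 366L, 365L)
}

# full daily time table for a span of years
make_time_table <- function(years, calendar = "noleap") {
  years <- sort(unique(as.integer(years)))
  nd <- days_in_year(years, calendar)
  data.frame(year = rep(years, nd),
             doy = unlist(lapply(nd, seq_len), use.names = FALSE))
}

#' One cell's daily temperature for one calendar year
#'
#' @param year integer calendar year.
#' @param temperature numeric vector of daily mean temperature (degC), one
#'   value per day of the year (365 or 366 values).
#' @param calendar `"noleap"` or `"gregorian"`.
#' @param lat,lon optional coordinates of the source cell.
#' @return object of class `daily_series`.
#' @export
daily_series <- function(year, temperature, calendar = "noleap",
                         lat = NA_real_, lon = NA_real_) {
  temperature <- as.numeric(temperature)
  if (!length(temperature) %in% c(365L, 366L))
    stop("a daily series must have 365 or 366 values, got ", length(temperature))
  if (calendar == "noleap" && length(temperature) != 365L)
    stop("noleap calendar years have exactly 365 days")
  structure(list(year = as.integer(year), temperature = temperature,
                 calendar = calendar, lat = lat, lon = lon),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> year %d (%d days, %s), mean %.2f degC\n",
              x$year, length(x$temperature), x$calendar, mean(x$temperature)))
  invisible(x)
}

#' Extract a single-cell annual series from a grid
#'
#' Picks the grid cell whose centre is nearest the requested point
#' (great-circle distance; ties resolved to the south-west neighbour) and
#' returns its daily series for one calendar year.
#'
#' @param grid a [climate_grid].
#' @param lat,lon query point in degrees.
#' @param year calendar year present in the grid.
#' @return a [daily_series].
#' @export
extract_series <- function(grid, lat, lon, year) {
  stopifnot(inherits(grid, "climate_grid"))
  if (lat < min(grid$lat) - 1e-9 || lat > max(grid$lat) + 1e-9 ||
      lon < min(grid$lon) - 1e-9 || lon > max(grid$lon) + 1e-9)
    stop(sprintf("point (%.4f, %.4f) lies outside the grid", lat, lon))
  if (!year %in% grid$time$year)
    stop(sprintf("year %d not present in grid (years %d-%d)", year,
                 min(grid$time$year), max(grid$time$year)))
  cells <- expand.grid(i = seq_along(grid$lat), j = seq_along(grid$lon))
  d <- gc_distance(lat, lon, grid$lat[cells$i], grid$lon[cells$j])
  # ties -> smallest latitude, then smallest longitude (south-west cell)
  ord <- order(round(d, 9), grid$lat[cells$i], grid$lon[cells$j])
  pick <- cells[ord[1], ]
  sel <- grid$time$year == year
  daily_series(year, grid$tas[pick$i, pick$j, sel], calendar = grid$calendar,
               lat = grid$lat[pick$i], lon = grid$lon[pick$j])
}

# great-circle distance (km) on a sphere, haversine
gc_distance <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  to_rad <- pi / 180
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlam / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

# indices of time steps falling in a set of years
time_index_years <- function(grid, years) which(grid$time$year %in% years)

# align two grids on their common (year, doy) steps; returns index pair
align_time <- function(a, b) {
  ka <- a$time$year * 1000L + a$time$doy
  kb <- b$time$year * 1000L + b$time$doy
  common <- intersect(ka, kb)
  list(i = match(common, ka), j = match(common, kb))
}
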