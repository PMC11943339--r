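#' Generate a synthetic elevation surface
#'
#' Builds a deterministic (seeded) digital elevation model on the config's
#' grid: a low western plain, a central massif rising above 1000 m, and
#' lower eastern hills, plus seeded small-scale roughness. At the default
#' domain and resolution the surface populates all three elevation bands
#' used by the gradient analysis (<500, 500-1000, >1000 m).
#'
#' @param config a [synth_config].
#' @return matrix `nlat x nlon` of elevation in metres (>= 0), with
#'   attributes `lat` and `lon`.
#' @export
generate_dem <- function(config) {
  ax <- grid_axes(config)
  nlat <- length(ax$lat); nlon <- length(ax$lon)
  if (nlat * nlon == 1)
    warning("single-cell domain: elevation/latitude gradient bins will be empty")
  latf <- (ax$lat - config$lat_range[1]) / diff(config$lat_range)
  lonf <- (ax$lon - config$lon_range[1]) / diff(config$lon_range)
  # gaussian hills at fixed fractional positions (latf, lonf, height m,
  # lat sd, lon sd): central massif, eastern hills, southern foothills
  hills <- rbind(c(0.42, 0.38, 1350, 0.14, 0.10),
                 c(0.65, 0.84,  820, 0.12, 0.08),
                 c(0.22, 0.52,  600, 0.12, 0.10))
  relief <- matrix(0, nlat, nlon)
  for (h in seq_len(nrow(hills))) {
    g <- outer(exp(-(latf - hills[h, 1])^2 / (2 * hills[h, 4]^2)),
               exp(-(lonf - hills[h, 2])^2 / (2 * hills[h, 5]^2)))
    relief <- relief + hills[h, 3] * g
  }
  set.seed(config$seed + 1000L)
  rough <- matrix(abs(stats::rnorm(nlat * nlon, sd = 45)), nlat, nlon)
  elev <- config$base_elevation_m + config$relief_amplitude * (relief + rough)
  elev <- pmax(elev, 0)
  attr(elev, "lat") <- ax$lat
  attr(elev, "lon") <- ax$lon
  elev
}

#' Warming path of the synthetic climate
#'
#' Per-year warming offsets (degC) relative to the baseline-period mean
#' state. Historical years follow the configured linear trend centred on the
#' baseline midpoint. Under a scenario, years from 2015 follow a ramp that
#' continues the historical path at 2014 and whose slope is solved so that
#' the 2081-2100 mean of the path minus its baseline-period mean equals the
#' scenario's configured warming exactly.
#'
#' @param config a [synth_config].
#' @param years integer vector of calendar years.
#' @param scenario optional [scenario_spec]; required if any year is past
#'   2014 and a scenario ramp is wanted.
#' @return numeric vector of warming offsets, one per year.
#' @export
warming_path <- function(config, years, scenario = NULL) {
  years <- as.numeric(years)
  gamma <- config$warming_rate / 10  # degC per year
  mid <- mean(config$baseline_years)
  hist_w <- function(y) gamma * (y - mid)
  if (is.null(scenario)) return(hist_w(years))
  stopifnot(inherits(scenario, "scenario_spec"))
  ramp_basis <- function(y) {
    dt <- pmax(y - 2014, 0)
    if (scenario$shape == "quadratic") dt^2 / (2090.5 - 2014) else dt
  }
  path <- function(slope, y)
    ifelse(y <= 2014, hist_w(y), hist_w(2014) + slope * ramp_basis(y))
  anchor <- 2081:2100
  anomaly <- function(slope)
    mean(path(slope, anchor)) - mean(path(slope, config$baseline_years))
  # anomaly is affine in the slope; solve exactly from two evaluations
  a0 <- anomaly(0); a1 <- anomaly(1)
  slope <- (scenario$warming_2090s - a0) / (a1 - a0)
  path(slope, years)
}

# mean-preserving west-amplified spatial pattern for scenario warming
west_pattern <- function(config, lon) {
  if (!config$west_amplified) return(rep(1, length(lon)))
  lonf <- (lon - config$lon_range[1]) / diff(config$lon_range)
  f <- 1 + 0.4 * (0.5 - lonf)
  f / mean(f)
}

# shared field builder behind the observed and pseudo-GCM generators.
# draw order (fixed so a zero-perturbation member reproduces the observed
# field bit for bit): interannual year effects over the full span, AR(1)
# innovations, member white noise.
synth_field <- function(config, dem, years, bias = 0, amplitude_factor = 1,
                        member_noise_sd = 0, seed_offset = 0L,
                        scenario = NULL, provenance = "observed") {
  ax <- grid_axes(config)
  if (!identical(dim(dem), c(length(ax$lat), length(ax$lon))))
    stop(sprintf("dem dimension [%s] does not match config grid [%d, %d]",
                 paste(dim(dem), collapse = ", "),
                 length(ax$lat), length(ax$lon)))
  years <- sort(unique(as.integer(years)))
  tt <- make_time_table(years, config$calendar)
  ntime <- nrow(tt)
  nlat <- length(ax$lat); nlon <- length(ax$lon); ncell <- nlat * nlon

  # static annual-mean surface
  latc <- mean(config$lat_range)
  mean_surface <- config$ref_mean_c +
    config$meridional_gradient * (matrix(ax$lat, nlat, nlon) - latc) +
    config$lapse_rate * dem / 1000

  # per-year offsets: warming path + shared interannual effect
  span <- min(years):max(years)
  set.seed(config$seed + as.integer(seed_offset) * 1009L + 11L)
  inter_span <- stats::rnorm(length(span), sd = config$interannual_sd)
  warm_span <- warming_path(config, span, scenario)
  year_offset <- (warm_span + inter_span)[match(years, span)]

  # seasonal cycle, minimum on day-of-year 15
  amp <- config$seasonal_amplitude * amplitude_factor
  seas <- -amp * cos(2 * pi * (tt$doy - 15) / 365)

  # AR(1) daily noise shared across the domain, continuous over the span
  rho <- config$noise_ar1
  if (config$noise_sd > 0) {
    innov <- stats::rnorm(ntime, sd = config$noise_sd * sqrt(1 - rho^2))
    innov[1] <- stats::rnorm(1, sd = config$noise_sd)
    noise <- as.numeric(stats::filter(innov, rho, method = "recursive"))
  } else {
    noise <- numeric(ntime)
  }

  step_offset <- year_offset[match(tt$year, years)] + seas + noise + bias
  tas <- array(mean_surface, dim = c(nlat, nlon, ntime))
  tas <- sweep(tas, 3, step_offset, "+")

  if (!is.null(scenario) && config$west_amplified) {
    wf <- west_pattern(config, ax$lon)
    ramp <- warm_span[match(tt$year, span)] -
      warming_path(config, tt$year, NULL)
    extra <- outer(rep(1, nlat), wf - 1)
    for (k in which(ramp != 0)) tas[, , k] <- tas[, , k] + extra * ramp[k]
  }

  if (member_noise_sd > 0)
    tas <- tas + array(stats::rnorm(ncell * ntime, sd = member_noise_sd),
                       dim = c(nlat, nlon, ntime))

  climate_grid(ax$lat, ax$lon, tt, tas, calendar = config$calendar,
               elevation = dem, provenance = provenance)
}

#' Generate the synthetic "observed" baseline climate
#'
#' Daily mean temperature on the config grid for the configured years:
#' annual-mean surface (reference mean, meridional gradient, elevation lapse)
#' plus baseline warming trend, shared interannual year effects, a seasonal
#' sinusoid, and AR(1) daily noise. Fully reproducible for a fixed seed.
#'
#' @param config a [synth_config].
#' @param dem elevation matrix from [generate_dem] (same grid).
#' @param years years to generate (default `config$years`).
#' @return a [climate_grid] with provenance `"observed"`.
#' @export
generate_observed_climate <- function(config, dem, years = config$years) {
  synth_field(config, dem, years, provenance = "observed")
}

#' Generate a pseudo-GCM member
#'
#' The observed-style synthetic field plus the member's additive bias,
#' seasonal-amplitude inflation and white noise, with the member's own
#' random draws. For years after 2014 a [scenario_spec] must be supplied and
#' its warming ramp is added, anchored so the 2081-2100 mean anomaly
#' relative to the baseline-period mean equals the configured warming.
#'
#' @param config a [synth_config].
#' @param dem elevation matrix on the config grid.
#' @param member a [pseudo_gcm_spec].
#' @param scenario a [scenario_spec], or `NULL` for historical-only years.
#' @param years years to generate.
#' @return a [climate_grid] with the member's name as provenance.
#' @export
generate_gcm_member <- function(config, dem, member, scenario = NULL,
                                years) {
  stopifnot(inherits(member, "pseudo_gcm_spec"))
  if (is.null(scenario) && any(years > 2014))
    stop("years after 2014 require a scenario_spec")
  if (!is.null(scenario)) stopifnot(inherits(scenario, "scenario_spec"))
  synth_field(config, dem, years,
              bias = member$bias,
              amplitude_factor = member$amplitude_factor,
              member_noise_sd = member$noise_sd,
              seed_offset = member$seed_offset,
              scenario = scenario,
              provenance = member$name)
}
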