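#' Configuration for the synthetic climate generator
#'
#' Describes the spatial domain, calendar, climatological structure and noise
#' model used to generate synthetic "observed" baseline grids and pseudo-GCM
#' scenario members. Defaults emulate a warm-temperate coastal province
#' (34.5-38.5 degN, annual means roughly 11-14 degC) on a 0.25 degree grid.
#'
#' The daily temperature model at a cell is
#' \deqn{T = \bar T_{cell} + w(y) + u_y + A\,s(d) + \epsilon_{d}}
#' where \eqn{\bar T_{cell}} combines the reference annual mean, a meridional
#' gradient and an elevation lapse term, \eqn{w(y)} is the warming path
#' (baseline linear trend, plus a scenario ramp for pseudo-GCM members),
#' \eqn{u_y} is an interannual year effect, \eqn{s(d)} a sinusoid with its
#' minimum on day-of-year 15, and \eqn{\epsilon_d} AR(1) daily noise with
#' stationary standard deviation `noise_sd` and lag-1 autocorrelation
#' `noise_ar1`, shared across the domain.
#'
#' @param lat_range,lon_range numeric length-2, domain bounds in degrees.
#' @param resolution grid resolution in degrees (> 0).
#' @param years integer vector of "observed" baseline generation years.
#' @param baseline_years years defining the baseline (current-period)
#'   climatology that scenario anomalies are anchored against.
#' @param calendar `"noleap"` (default; 365-day) or `"gregorian"`.
#' @param ref_mean_c annual-mean temperature (degC) at the domain-centre
#'   latitude at sea level.
#' @param meridional_gradient degC per degree latitude (negative northward).
#' @param lapse_rate degC per km of elevation (negative upward).
#' @param seasonal_amplitude amplitude of the seasonal sinusoid (degC, >= 0).
#' @param noise_sd stationary SD of AR(1) daily noise (degC, >= 0).
#' @param noise_ar1 lag-1 autocorrelation of daily noise (|rho| < 1).
#' @param interannual_sd SD of the shared year effect (degC, >= 0).
#' @param warming_rate baseline linear warming (degC per decade).
#' @param base_elevation_m,relief_amplitude DEM base level (m) and a
#'   dimensionless scale on the synthetic relief (0 gives a flat DEM at the
#'   base level).
#' @param west_amplified logical; if `TRUE`, scenario warming is amplified in
#'   the west of the domain (mean-preserving spatial pattern).
#' @param seed integer random seed (mandatory; there is no silent default).
#'
#' @return object of class `synth_config`.
#' @export
synth_config <- function(lat_range = c(34.5, 38.5),
                         lon_range = c(114.5, 122.75),
                         resolution = 0.25,
                         years = 1979:2018,
                         baseline_years = 1979:2018,
                         calendar = c("noleap", "gregorian"),
                         ref_mean_c = 14.2,
                         meridional_gradient = -0.8,
                         lapse_rate = -6.5,
                         seasonal_amplitude = 14,
                         noise_sd = 2,
                         noise_ar1 = 0.7,
                         interannual_sd = 0.3,
                         warming_rate = 0.3,
                         base_elevation_m = 30,
                         relief_amplitude = 1,
                         west_amplified = FALSE,
                         seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("'seed' is mandatory in a synth_config; there is no default")
  calendar <- match.arg(calendar)
  stopifnot(resolution > 0,
            lat_range[2] > lat_range[1], lon_range[2] > lon_range[1],
            seasonal_amplitude >= 0, noise_sd >= 0, interannual_sd >= 0,
            abs(noise_ar1) < 1, relief_amplitude >= 0, base_elevation_m >= 0)
  cfg <- list(lat_range = as.numeric(lat_range),
              lon_range = as.numeric(lon_range),
              resolution = resolution,
              years = as.integer(years),
              baseline_years = as.integer(baseline_years),
              calendar = calendar,
              ref_mean_c = ref_mean_c,
              meridional_gradient = meridional_gradient,
              lapse_rate = lapse_rate,
              seasonal_amplitude = seasonal_amplitude,
              noise_sd = noise_sd,
              noise_ar1 = noise_ar1,
              interannual_sd = interannual_sd,
              warming_rate = warming_rate,
              base_elevation_m = base_elevation_m,
              relief_amplitude = relief_amplitude,
              west_amplified = west_amplified,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %.2f-%.2f degN x %.2f-%.2f degE @ %.3g deg, %s\n",
              x$lat_range[1], x$lat_range[2], x$lon_range[1], x$lon_range[2],
              x$resolution, x$calendar))
  cat(sprintf("  years %d-%d, ref mean %.1f degC, amp %.1f, noise sd %.1f (rho %.2f)\n",
              min(x$years), max(x$years), x$ref_mean_c, x$seasonal_amplitude,
              x$noise_sd, x$noise_ar1))
  cat(sprintf("  trend %.2f degC/decade, interannual sd %.2f, seed %d\n",
              x$warming_rate, x$interannual_sd, x$seed))
  invisible(x)
}

# cell-centre coordinate vectors for a config
grid_axes <- function(config) {
  list(lat = seq(config$lat_range[1] + config$resolution / 2,
                 config$lat_range[2], by = config$resolution),
       lon = seq(config$lon_range[1] + config$resolution / 2,
                 config$lon_range[2], by = config$resolution))
}

#' Climate-change scenario description
#'
#' @param name one of `"SSP1-2.6"`, `"SSP2-4.5"`, `"SSP3-7.0"`, `"SSP5-8.5"`.
#' @param warming_2090s warming by the 2090s (2081-2100 mean anomaly relative
#'   to the baseline-period mean), degC.
#' @param shape warming-ramp shape over 2015-2100: `"linear"` or
#'   `"quadratic"`.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, warming_2090s,
                          shape = c("linear", "quadratic")) {
  valid <- c("SSP1-2.6", "SSP2-4.5", "SSP3-7.0", "SSP5-8.5")
  if (!name %in% valid)
    stop(sprintf("unknown scenario '%s'; valid names: %s", name,
                 paste(valid, collapse = ", ")))
  if (!is.finite(warming_2090s)) stop("'warming_2090s' must be finite")
  shape <- match.arg(shape)
  structure(list(name = name, warming_2090s = warming_2090s, shape = shape),
            class = "scenario_spec")
}

#' Default scenario set
#'
#' The four SSP scenarios with end-of-century (2081-2100 mean) warming of
#' 2.37, 3.45, 4.35 and 5.49 degC relative to the 1979-2018 baseline,
#' spanning low to high radiative forcing.
#'
#' @return named list of [scenario_spec] objects.
#' @export
default_scenarios <- function() {
  w <- c("SSP1-2.6" = 2.37, "SSP2-4.5" = 3.45,
         "SSP3-7.0" = 4.35, "SSP5-8.5" = 5.49)
  out <- lapply(names(w), function(nm) scenario_spec(nm, w[[nm]]))
  names(out) <- names(w)
  out
}

#' Pseudo-GCM member description
#'
#' A pseudo-GCM perturbs the synthetic "observed" climate with an additive
#' bias, a seasonal-amplitude inflation factor, extra white noise, and its
#' own noise seed, so that ensemble evaluation and selection have real
#' differences to work on.
#'
#' @param name member label.
#' @param bias additive temperature bias (degC).
#' @param amplitude_factor multiplies the seasonal amplitude (> 0).
#' @param noise_sd SD of additional member-specific white noise (degC).
#' @param seed_offset integer added to the config seed for this member's
#'   random draws.
#' @return object of class `pseudo_gcm_spec`.
#' @export
pseudo_gcm_spec <- function(name, bias = 0, amplitude_factor = 1,
                            noise_sd = 0, seed_offset = 0) {
  if (amplitude_factor <= 0) stop("'amplitude_factor' must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(name = as.character(name), bias = bias,
                 amplitude_factor = amplitude_factor, noise_sd = noise_sd,
                 seed_offset = as.integer(seed_offset)),
            class = "pseudo_gcm_spec")
}

#' Default pseudo-GCM ensemble
#'
#' Five members spanning small to substantial bias, amplitude inflation and
#' noise, so that skill ranking and member selection are non-trivial.
#'
#' @return named list of [pseudo_gcm_spec] objects.
#' @export
default_members <- function() {
  specs <- list(
    pseudo_gcm_spec("pgcm-alpha",   bias =  0.05, amplitude_factor = 1.00,
                    noise_sd = 0.2, seed_offset = 1L),
    pseudo_gcm_spec("pgcm-bravo",   bias =  0.30, amplitude_factor = 1.05,
                    noise_sd = 0.5, seed_offset = 2L),
    pseudo_gcm_spec("pgcm-charlie", bias = -0.50, amplitude_factor = 0.95,
                    noise_sd = 0.8, seed_offset = 3L),
    pseudo_gcm_spec("pgcm-delta",   bias =  0.80, amplitude_factor = 1.15,
                    noise_sd = 1.2, seed_offset = 4L),
    pseudo_gcm_spec("pgcm-echo",    bias = -1.20, amplitude_factor = 0.85,
                    noise_sd = 1.5, seed_offset = 5L))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}
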