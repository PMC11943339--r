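# shared fixtures, built in code at test time

# small single-cell config: flat terrain, deterministic unless asked
tiny_config <- function(seed = 1, years = 1979:1983, ...) {
  synth_config(lat_range = c(35, 36), lon_range = c(117, 118),
               resolution = 1, years = years, seed = seed, ...)
}

# coarse multi-cell config (2 x 4 cells) for fast field-level tests
coarse_config <- function(seed = 1, years = 1979:1983, ...) {
  synth_config(lat_range = c(34.5, 38.5), lon_range = c(114.5, 122.5),
               resolution = 2, years = years, seed = seed, ...)
}

# deterministic noise-free config
quiet_config <- function(seed = 1, constructor = coarse_config, ...) {
  constructor(seed = seed, noise_sd = 0, interannual_sd = 0, ...)
}

# build a climate_grid directly from a [nlat, nlon, ntime] array
manual_grid <- function(tas, lat = NULL, lon = NULL, years = 2000,
                        calendar = "noleap", elevation = NULL,
                        provenance = "observed") {
  d <- dim(tas)
  if (is.null(lat)) lat <- seq(35, by = 0.5, length.out = d[1])
  if (is.null(lon)) lon <- seq(117, by = 0.5, length.out = d[2])
  tt <- voltigrid:::make_time_table(years, calendar)
  stopifnot(nrow(tt) == d[3])
  climate_grid(lat, lon, tt, tas, calendar = calendar,
               elevation = elevation, provenance = provenance)
}

# single-cell grid from one or more stacked annual series
series_grid <- function(values, years, ...) {
  manual_grid(array(values, c(1, 1, length(values))), years = years, ...)
}

# independent naive oracles ------------------------------------------------

naive_cgdd <- function(temps, t0) {
  total <- 0
  for (t in temps) if (t > t0) total <- total + (t - t0)
  total
}

# OLS slope/intercept via explicit normal equations
naive_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Taylor statistics from the defining sums, written independently
naive_taylor <- function(s, o) {
  n <- length(s)
  ms <- sum(s) / n; mo <- sum(o) / n
  vs <- sum((s - ms)^2) / n; vo <- sum((o - mo)^2) / n
  cov <- sum((s - ms) * (o - mo)) / n
  crmse2 <- sum(((s - ms) - (o - mo))^2) / n
  list(r = cov / sqrt(vs * vo), sd_sim = sqrt(vs), sd_obs = sqrt(vo),
       crmse = sqrt(crmse2), bias = ms - mo)
}
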