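#' Elevation and latitude binning scheme
#'
#' Defaults follow the study stratification: three elevation bands
#' (<500 m, 500-1000 m, >1000 m; boundary convention [0,500), [500,1000],
#' (1000, Inf)) and five left-open/right-closed latitude bands
#' ((34.5,35], (35,36], (36,37], (37,38], (38,38.5] degN).
#'
#' @param elevation_breaks interior elevation break points (m).
#' @param latitude_breaks full latitude break points (degN).
#' @return object of class `gradient_binning`.
#' @export
gradient_binning <- function(elevation_breaks = c(500, 1000),
                             latitude_breaks = c(34.5, 35, 36, 37, 38, 38.5)) {
  stopifnot(length(elevation_breaks) == 2, diff(elevation_breaks) > 0,
            all(diff(latitude_breaks) > 0))
  eb <- elevation_breaks
  elev_labels <- c(sprintf("<%g m", eb[1]), sprintf("%g-%g m", eb[1], eb[2]),
                   sprintf(">%g m", eb[2]))
  lat_labels <- sprintf("(%g-%g degN]", utils::head(latitude_breaks, -1),
                        latitude_breaks[-1])
  structure(list(elevation_breaks = eb, latitude_breaks = latitude_breaks,
                 elevation_labels = elev_labels, latitude_labels = lat_labels),
            class = "gradient_binning")
}

#' Assign grid cells to elevation and latitude bins
#'
#' Elevation: `[0, b1)` -> first bin, `[b1, b2]` -> middle bin,
#' `(b2, Inf)` -> last bin (so exactly 500 m and exactly 1000 m both fall
#' in the middle band at the defaults). Latitude intervals are left-open,
#' right-closed. Cells outside every latitude bin are masked with a
#' warning.
#'
#' @param dem elevation matrix `[lat, lon]` (m).
#' @param lat latitudes of the rows of `dem` (degN).
#' @param binning a [gradient_binning].
#' @return list with factors `elevation_bin` and `latitude_bin`, each of
#'   length `length(dem)` in column-major cell order, plus `dim`.
#' @export
assign_bins <- function(dem, lat, binning = gradient_binning()) {
  stopifnot(inherits(binning, "gradient_binning"),
            nrow(dem) == length(lat))
  eb <- binning$elevation_breaks
  ei <- ifelse(as.vector(dem) < eb[1], 1L,
               ifelse(as.vector(dem) <= eb[2], 2L, 3L))
  elev_bin <- factor(binning$elevation_labels[ei],
                     levels = binning$elevation_labels)
  lb <- binning$latitude_breaks
  li <- findInterval(lat, lb, left.open = TRUE)  # (a, b] intervals
  li[lat <= lb[1] | lat > lb[length(lb)]] <- NA
  if (anyNA(li))
    warning(sum(is.na(li)) * ncol(dem),
            " cell(s) fall outside all latitude bins and are masked")
  lat_bin <- factor(rep(binning$latitude_labels[li], ncol(dem)),
                    levels = binning$latitude_labels)
  list(elevation_bin = elev_bin, latitude_bin = lat_bin,
       dim = dim(dem))
}

#' Per-bin period means of a voltinism field
#'
#' Unweighted mean over the member cells of each bin and the years of the
#' period (cells are near-equal-area over a domain a few degrees tall;
#' see the package vignette).
#'
#' @param field a [cgdd_field] result.
#' @param membership a factor matrix from [assign_bins] (one axis).
#' @param years period years.
#' @param what `"voltinism"` or `"cgdd"`.
#' @return named numeric vector of bin means (NA for empty bins).
#' @export
bin_period_mean <- function(field, membership, years,
                            what = c("voltinism", "cgdd")) {
  what <- match.arg(what)
  m <- period_mean(field, years, what)
  out <- tapply(as.vector(m), as.vector(membership), mean, na.rm = TRUE,
                default = NA_real_)
  stats::setNames(as.numeric(out), dimnames(out)[[1]])
}

#' Per-bin annual series of a voltinism field
#'
#' @inheritParams bin_period_mean
#' @return matrix bins x years of annual bin means.
#' @export
bin_annual_series <- function(field, membership, what = c("voltinism", "cgdd")) {
  what <- match.arg(what)
  out <- vapply(field$years, function(y)
    bin_period_mean(field, membership, y, what),
    numeric(nlevels(membership)))
  out <- matrix(out, nrow = nlevels(membership),
                dimnames = list(levels(membership), field$years))
  out
}

#' Decadal trend of an annual series
#'
#' Ordinary least squares of the annual value on the calendar year, with
#' the slope reported per decade and a t-based 95% confidence interval.
#' A zero-variance (constant) series returns slope 0 and R-squared 0 by
#' convention.
#'
#' @param values annual values.
#' @param years calendar years (same length, >= 3).
#' @param conf confidence level for the slope interval.
#' @return object of class `trend_estimate`: `slope_per_decade`,
#'   `intercept`, `ci_low`, `ci_high`, `r_squared`, `n`.
#' @export
decadal_trend <- function(values, years, conf = 0.95) {
  ok <- is.finite(values) & is.finite(years)
  values <- values[ok]; years <- years[ok]
  if (length(values) < 3) stop("a trend needs at least 3 years")
  if (stats::sd(values) == 0) {
    out <- list(slope_per_decade = 0, intercept = values[1], ci_low = 0,
                ci_high = 0, r_squared = 0, n = length(values))
  } else {
    fit <- stats::lm(values ~ years)
    n <- length(values)
    rss <- sum(stats::residuals(fit)^2)
    se <- sqrt(rss / (n - 2) / sum((years - mean(years))^2))
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 2)
    slope <- unname(stats::coef(fit)["years"])
    r2 <- 1 - rss / sum((values - mean(values))^2)
    out <- list(slope_per_decade = slope * 10,
                intercept = unname(stats::coef(fit)[1]),
                ci_low = (slope - tq * se) * 10,
                ci_high = (slope + tq * se) * 10,
                r_squared = r2, n = n)
  }
  structure(out, class = "trend_estimate")
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf("<trend_estimate> slope %.4f per decade (95%% CI %.4f..%.4f), R2 = %.3f, n = %d\n",
              x$slope_per_decade, x$ci_low, x$ci_high, x$r_squared, x$n))
  invisible(x)
}

#' Voltinism-change versus warming regression
#'
#' OLS of pooled voltinism anomalies on temperature anomalies (both
#' relative to the baseline-period mean), giving the sensitivity in
#' generations per degC, plus predicted voltinism changes at +1.0, +1.5 and
#' +2.0 degC.
#'
#' @param delta_t temperature anomalies (degC).
#' @param delta_n voltinism anomalies (generations), same length (>= 3).
#' @return object of class `voltinism_regression`: `slope_per_degc`,
#'   `intercept`, `r_squared`, `n`, and `predicted` at the three reporting
#'   points.
#' @export
voltinism_temperature_regression <- function(delta_t, delta_n) {
  ok <- is.finite(delta_t) & is.finite(delta_n)
  delta_t <- delta_t[ok]; delta_n <- delta_n[ok]
  if (length(delta_t) < 3) stop("a regression needs at least 3 points")
  fit <- stats::lm(delta_n ~ delta_t)
  co <- stats::coef(fit)
  at <- c(1, 1.5, 2)
  r2 <- if (stats::sd(delta_n) == 0) 1 else
    1 - sum(stats::residuals(fit)^2) / sum((delta_n - mean(delta_n))^2)
  structure(list(slope_per_degc = unname(co["delta_t"]),
                 intercept = unname(co[1]),
                 r_squared = r2,
                 n = length(delta_t),
                 predicted = stats::setNames(unname(co[1] + co["delta_t"] * at),
                                             paste0("dN_at_", at, "C"))),
            class = "voltinism_regression")
}

#' @export
print.voltinism_regression <- function(x, ...) {
  cat(sprintf("<voltinism_regression> %.4f generations per degC (R2 = %.3f, n = %d)\n",
              x$slope_per_degc, x$r_squared, x$n))
  cat(sprintf("  predicted dN at +1 / +1.5 / +2 degC: %.3f / %.3f / %.3f\n",
              x$predicted[1], x$predicted[2], x$predicted[3]))
  invisible(x)
}
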