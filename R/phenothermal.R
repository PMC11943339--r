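#' Developmental parameters of the pine caterpillar
#'
#' Stage-wise and whole-generation developmental zero (T0, degC) and
#' effective temperature accumulation (K, degree-days) with standard
#' errors, from rearing experiments under natural variable temperature.
#' The packaged defaults are for *Dendrolimus spectabilis*: complete
#' generation T0 = 9.95 +/- 0.61 degC, K = 1698.18 +/- 48.18 degree-days,
#' with stages "larvae after overwintering", "pupae", "egg" and "larvae
#' before overwintering".
#'
#' @param source a CSV path with columns `stage`, `t0_c`, `t0_se`, `k_dd`,
#'   `k_se` (one row per stage plus a `complete_generation` row), a data
#'   frame with those columns, or `NULL` for the packaged defaults.
#' @return object of class `dev_params`: the parameter table plus `t0`,
#'   `t0_se`, `k`, `k_se` for the complete generation.
#' @export
dev_params <- function(source = NULL) {
  tab <- if (is.null(source)) {
    utils::read.csv(system.file("extdata", "developmental_parameters.csv",
                                package = "voltigrid"))
  } else if (is.character(source)) {
    utils::read.csv(source)
  } else {
    as.data.frame(source)
  }
  need <- c("stage", "t0_c", "t0_se", "k_dd", "k_se")
  if (!all(need %in% names(tab)))
    stop("parameter table needs columns: ", paste(need, collapse = ", "))
  if (!"complete_generation" %in% tab$stage)
    stop("parameter table needs a 'complete_generation' row")
  if (any(tab$k_dd <= 0)) stop("every stage K must be positive")
  if (any(tab$t0_se < 0 | tab$k_se < 0)) stop("standard errors must be >= 0")
  cg <- tab[tab$stage == "complete_generation", ]
  obj <- structure(list(table = tab, t0 = cg$t0_c, t0_se = cg$t0_se,
                        k = cg$k_dd, k_se = cg$k_se),
                   class = "dev_params")
  chk <- stage_table_consistency(obj)
  if (nrow(tab) > 1 && !chk$pass)
    warning(sprintf(paste0("stage K values sum to %.2f but the complete-",
                           "generation K is %.2f (difference %.2f > 0.02)"),
                    chk$stage_sum, chk$total, chk$difference))
  obj
}

#' @export
print.dev_params <- function(x, ...) {
  cat(sprintf("<dev_params> complete generation: T0 = %.2f +/- %.2f degC, K = %.2f +/- %.2f dd\n",
              x$t0, x$t0_se, x$k, x$k_se))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Check stage-sum consistency of the parameter table
#'
#' The effective temperature accumulations of the four developmental stages
#' should add up to the complete-generation K up to rounding of the printed
#' values (0.02 degree-days).
#'
#' @param params a [dev_params].
#' @return list with `stage_sum`, `total` (complete-generation K),
#'   `difference` (absolute) and `pass` (difference <= 0.02).
#' @export
stage_table_consistency <- function(params) {
  stopifnot(inherits(params, "dev_params"))
  stages <- params$table[params$table$stage != "complete_generation", ]
  ssum <- sum(stages$k_dd)
  diff <- abs(ssum - params$k)
  list(stage_sum = ssum, total = params$k, difference = diff,
       pass = diff <= 0.02)
}

#' Cumulative growing degree-days for one calendar year
#'
#' CGDD = sum over all days of max(Ti - T0, 0): only the exceedance of the
#' daily mean temperature over the developmental zero accrues, with no
#' upper cutoff.
#'
#' @param series a [daily_series] or a plain numeric vector of daily mean
#'   temperatures (degC) covering one calendar year.
#' @param t0 developmental zero (degC), or a [dev_params] whose
#'   complete-generation T0 is used.
#' @return CGDD in degree-days (>= 0).
#' @export
compute_cgdd <- function(series, t0) {
  x <- if (inherits(series, "daily_series")) series$temperature else
    as.numeric(series)
  if (length(x) == 0) stop("empty temperature series")
  if (any(!is.finite(x))) stop("non-finite daily temperature in series")
  if (inherits(t0, "dev_params")) t0 <- t0$t0
  sum(pmax(x - t0, 0))
}

#' Voltinism from annual degree-day accumulation
#'
#' The number of generations per year is the continuous ratio N = CGDD / K;
#' it is deliberately not floored, so fractional generations are reported.
#'
#' @param cgdd annual CGDD (degree-days, >= 0); vectorized.
#' @param params a [dev_params], or a single numeric K.
#' @return voltinism in generations per year.
#' @export
compute_voltinism <- function(cgdd, params) {
  k <- if (inherits(params, "dev_params")) params$k else as.numeric(params)
  if (k <= 0) stop("effective temperature accumulation K must be positive")
  if (any(cgdd < 0, na.rm = TRUE)) stop("CGDD must be nonnegative")
  cgdd / k
}

#' Per-cell annual CGDD and voltinism over a grid
#'
#' Applies the degree-day accumulation and the voltinism ratio to every
#' cell and every complete calendar year of the grid. Partial years at the
#' grid's time edges are dropped with a warning.
#'
#' @param grid a [climate_grid].
#' @param params a [dev_params] (defaults to the packaged pine-caterpillar
#'   parameters).
#' @return object of class `voltinism_field`: per-cell, per-year `cgdd` and
#'   `voltinism` arrays `[lat, lon, year]` plus coordinates, years, the
#'   parameters used, and the elevation field if the grid carried one.
#' @export
cgdd_field <- function(grid, params = dev_params()) {
  stopifnot(inherits(grid, "climate_grid"))
  cnt <- table(grid$time$year)
  full <- days_in_year(as.integer(names(cnt)), grid$calendar)
  complete <- as.integer(names(cnt))[as.integer(cnt) == full]
  dropped <- setdiff(as.integer(names(cnt)), complete)
  if (length(dropped))
    warning("dropping partial year(s) at the time edges: ",
            paste(dropped, collapse = ", "))
  if (!length(complete)) stop("no complete calendar year in grid")
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  cg <- array(NA_real_, c(nlat, nlon, length(complete)))
  excess <- pmax(grid$tas - params$t0, 0)
  for (yi in seq_along(complete)) {
    sel <- grid$time$year == complete[yi]
    cg[, , yi] <- rowSums(excess[, , sel, drop = FALSE], dims = 2)
  }
  structure(list(lat = grid$lat, lon = grid$lon, years = complete,
                 cgdd = cg, voltinism = cg / params$k, params = params,
                 elevation = grid$elevation, provenance = grid$provenance),
            class = "voltinism_field")
}

#' @export
print.voltinism_field <- function(x, ...) {
  cat(sprintf("<voltinism_field> %s: %d x %d cells, years %d-%d\n",
              x$provenance, length(x$lat), length(x$lon), min(x$years),
              max(x$years)))
  cat(sprintf("  CGDD mean %.1f dd [%.1f, %.1f]\n",
              mean(x$cgdd, na.rm = TRUE), min(x$cgdd, na.rm = TRUE),
              max(x$cgdd, na.rm = TRUE)))
  cat(sprintf("  voltinism mean %.3f [%.3f, %.3f] generations/yr\n",
              mean(x$voltinism, na.rm = TRUE), min(x$voltinism, na.rm = TRUE),
              max(x$voltinism, na.rm = TRUE)))
  invisible(x)
}

#' Period-mean map of a voltinism field
#'
#' @param field a [cgdd_field] result.
#' @param years years of the period (must all be present).
#' @param what `"voltinism"` or `"cgdd"`.
#' @return matrix `[lat, lon]` of per-cell period means.
#' @export
period_mean <- function(field, years, what = c("voltinism", "cgdd")) {
  what <- match.arg(what)
  stopifnot(inherits(field, "voltinism_field"))
  sel <- field$years %in% years
  if (!any(sel)) stop("none of the requested years are in the field")
  apply(field[[what]][, , sel, drop = FALSE], c(1, 2), mean)
}

#' Change in voltinism between two period means
#'
#' Per-cell difference future minus baseline; positive values denote an
#' increase in the number of generations per year.
#'
#' @param future,baseline per-cell period-mean matrices (from
#'   [period_mean]) on the same grid.
#' @return matrix of voltinism differences.
#' @export
delta_voltinism <- function(future, baseline) {
  if (!identical(dim(future), dim(baseline)))
    stop(sprintf("grid mismatch: future is [%s], baseline is [%s]",
                 paste(dim(future), collapse = ", "),
                 paste(dim(baseline), collapse = ", ")))
  future - baseline
}

#' Parameter-uncertainty band for annual voltinism
#'
#' Propagates the reported standard errors of T0 and K through the
#' degree-day model for one annual series: the low bound recomputes CGDD
#' with T0 + SE and divides by K + SE; the high bound uses T0 - SE and
#' K - SE. The band always contains the point estimate.
#'
#' @param series a [daily_series] or numeric vector of one year's daily
#'   temperatures.
#' @param params a [dev_params].
#' @return list with `low`, `n` (point estimate) and `high` voltinism.
#' @export
parameter_uncertainty_band <- function(series, params) {
  stopifnot(inherits(params, "dev_params"))
  n <- compute_voltinism(compute_cgdd(series, params$t0), params$k)
  low <- compute_voltinism(compute_cgdd(series, params$t0 + params$t0_se),
                           params$k + params$k_se)
  high <- compute_voltinism(compute_cgdd(series, params$t0 - params$t0_se),
                            params$k - params$k_se)
  list(low = low, n = n, high = high)
}

#' Quick-look map of a period-mean field
#'
#' @param x a [cgdd_field] result.
#' @param years years to average (default: all).
#' @param what `"voltinism"` or `"cgdd"`.
#' @param ... passed to [graphics::image].
#' @export
plot.voltinism_field <- function(x, years = x$years,
                                 what = c("voltinism", "cgdd"), ...) {
  what <- match.arg(what)
  m <- period_mean(x, years, what)
  graphics::image(x$lon, x$lat, t(m), xlab = "longitude (degE)",
                  ylab = "latitude (degN)",
                  main = sprintf("%s, %d-%d", what, min(years), max(years)),
                  col = grDevices::hcl.colors(24, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}
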