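test_that("bin boundaries follow the stated interval conventions", {
  b <- gradient_binning()
  dem <- matrix(c(499.99, 500, 1000, 1000.01, 0, 2000), 1, 6)
  bins <- assign_bins(dem, 35.2, b)
  expect_equal(as.character(bins$elevation_bin),
               c("<500 m", "500-1000 m", "500-1000 m", ">1000 m",
                 "<500 m", ">1000 m"))
  # latitude intervals are left-open, right-closed
  dem2 <- matrix(100, 4, 1)
  bins2 <- assign_bins(dem2, c(35, 35.0001, 38.5, 36), b)
  expect_equal(as.character(bins2$latitude_bin),
               c("(34.5-35 degN]", "(35-36 degN]", "(38-38.5 degN]",
                 "(35-36 degN]"))
  expect_warning(out <- assign_bins(matrix(100, 2, 1), c(34.5, 40), b),
                 "masked")
  expect_true(all(is.na(out$latitude_bin)))
})

test_that("bins partition the domain", {
  cfg <- synth_config(seed = 1)
  dem <- generate_dem(cfg)
  bins <- assign_bins(dem, attr(dem, "lat"))
  expect_equal(sum(table(bins$elevation_bin)), length(dem))
  expect_equal(sum(table(bins$latitude_bin)), length(dem))
  tab <- table(bins$elevation_bin, bins$latitude_bin)
  expect_equal(sum(tab), length(dem))
})

test_that("bin period means reduce to simple averages", {
  # two cells, voltinism 1.2 and 1.4 in one bin -> 1.3
  g <- manual_grid(array(c(16, 18), c(1, 2, 365)), lat = 35.2,
                   lon = c(117, 118))
  p <- dev_params(data.frame(stage = "complete_generation", t0_c = 10,
                             t0_se = 0, k_dd = 365, k_se = 0))
  f <- cgdd_field(g, p)  # voltinism 6 and 8
  memb <- factor(c("low", "low"), levels = c("low", "high"))
  m <- bin_period_mean(f, memb, 2000)
  expect_equal(unname(m["low"]), 7)
  expect_true(is.na(m["high"]))
  # single-cell bin with a constant field returns the constant
  memb2 <- factor(c("a", "b"), levels = c("a", "b"))
  expect_equal(unname(bin_period_mean(f, memb2, 2000)), c(6, 8))
  ser <- bin_annual_series(f, memb2)
  expect_equal(dim(ser), c(2L, 1L))
  expect_equal(unname(ser[, 1]), c(6, 8))
})

test_that("decadal trends match the closed form and the OLS oracle", {
  years <- 2000:2009
  expect_error(decadal_trend(c(1, 2), c(2000, 2001)), "3 years")
  const <- decadal_trend(rep(3.3, 10), years)
  expect_equal(const$slope_per_decade, 0)
  expect_equal(const$r_squared, 0)
  line <- decadal_trend(2 * (years - 2000), years)
  expect_equal(line$slope_per_decade, 20, tolerance = 1e-9)
  expect_equal(line$r_squared, 1, tolerance = 1e-12)
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    yr <- sort(sample(1979:2100, n))
    v <- 0.05 * yr + rnorm(n, sd = 2)
    tr <- decadal_trend(v, yr)
    or <- naive_ols(yr, v)
    expect_equal(tr$slope_per_decade, or$slope * 10, tolerance = 1e-9)
    expect_equal(tr$intercept, or$intercept, tolerance = 1e-9)
    expect_equal(tr$r_squared, or$r2, tolerance = 1e-9)
    expect_true(tr$ci_low <= tr$slope_per_decade &&
                  tr$slope_per_decade <= tr$ci_high)
  }
})

test_that("the warming regression recovers exact lines and pools duplicates", {
  k <- 1698.18
  dt <- seq(0.2, 3, by = 0.2)
  fit <- voltinism_temperature_regression(dt, 365 / k * dt)
  expect_equal(fit$slope_per_degc, 365 / k, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(fit$predicted["dN_at_1.5C"]), 365 / k * 1.5,
               tolerance = 1e-9)
  # duplicated points act as implicit weights: same fit as the oracle says
  dt2 <- c(1, 1, 2, 3); dn2 <- c(0.1, 0.3, 0.35, 0.6)
  fit2 <- voltinism_temperature_regression(dt2, dn2)
  or <- naive_ols(dt2, dn2)
  expect_equal(fit2$slope_per_degc, or$slope, tolerance = 1e-12)
  expect_error(voltinism_temperature_regression(c(1, 2), c(1, 2)), "3 points")
})

test_that("synthetic warming yields slopes between zero and the analytic cap", {
  # seasonal series put winter days below threshold, so the realized
  # sensitivity must fall strictly inside (0, 365/K)
  p <- dev_params()
  cfg <- quiet_config(seed = 2)
  dem <- generate_dem(cfg)
  m <- pseudo_gcm_spec("m", seed_offset = 1)
  sc <- default_scenarios()[["SSP5-8.5"]]
  yrs <- c(1979:2018, seq(2020, 2100, by = 8))
  g <- generate_gcm_member(cfg, dem, m, sc, yrs)
  f <- cgdd_field(g, p)
  base <- f$years <= 2018
  ann_n <- apply(f$voltinism, 3, mean)
  ann_t <- annual_mean_series(g)
  dn <- ann_n[!base] - mean(ann_n[base])
  dt <- ann_t[!base] - mean(ann_t[base])
  fit <- voltinism_temperature_regression(dt, dn)
  expect_gt(fit$slope_per_degc, 0)
  expect_lt(fit$slope_per_degc, 365 / p$k)
  expect_gt(fit$r_squared, 0.8)
})

test_that("configured warming trends are recovered from CGDD fields", {
  # July-centred warm season crossing the threshold: with all days above
  # T0 the decadal CGDD trend equals 365 * beta exactly; seasonal defaults
  # must land in (0, 365 * beta)
  p <- dev_params()
  beta <- 0.5
  cfg_warm <- quiet_config(constructor = tiny_config, warming_rate = beta,
                           ref_mean_c = 25, seasonal_amplitude = 5,
                           years = 1979:2018)
  g <- generate_observed_climate(cfg_warm, matrix(0, 1, 1))
  f <- cgdd_field(g, p)
  tr <- decadal_trend(apply(f$cgdd, 3, mean), f$years)
  expect_equal(tr$slope_per_decade, 365 * beta, tolerance = 1e-6)
  cfg_seas <- quiet_config(constructor = tiny_config, warming_rate = beta,
                           years = 1979:2018)
  g2 <- generate_observed_climate(cfg_seas, matrix(0, 1, 1))
  tr2 <- decadal_trend(apply(cgdd_field(g2, p)$cgdd, 3, mean),
                       cgdd_field(g2, p)$years)
  expect_gt(tr2$slope_per_decade, 0)
  expect_lt(tr2$slope_per_decade, 365 * beta)
  # noisy recovery: the 95% CI covers the all-above-threshold expectation
  hits <- vapply(1:20, function(seed) {
    cfgn <- tiny_config(seed = seed, warming_rate = beta, ref_mean_c = 25,
                        seasonal_amplitude = 5, years = 1979:2018)
    gn <- generate_observed_climate(cfgn, matrix(0, 1, 1))
    trn <- decadal_trend(apply(cgdd_field(gn, p)$cgdd, 3, mean),
                         cgdd_field(gn, p)$years)
    trn$ci_low <= 365 * beta && 365 * beta <= trn$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
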