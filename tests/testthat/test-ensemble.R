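test_that("Taylor statistics recover identity and pure-bias cases", {
  cfg <- coarse_config(seed = 6)
  dem <- generate_dem(cfg)
  obs <- generate_observed_climate(cfg, dem, years = 2000:2004)
  twin <- generate_gcm_member(cfg, dem, pseudo_gcm_spec("twin"), NULL,
                              years = 2000:2004)
  ts <- taylor_statistics(twin, obs)
  expect_equal(ts$r, 1)
  expect_equal(ts$crmse, 0)
  expect_equal(ts$sd_norm, 1)
  expect_equal(ts$bias, 0)
  expect_equal(skill_score(ts), 1)
  shifted <- generate_gcm_member(cfg, dem, pseudo_gcm_spec("hot", bias = 2),
                                 NULL, years = 2000:2004)
  tb <- taylor_statistics(shifted, obs)
  expect_equal(tb$r, 1, tolerance = 1e-12)
  expect_equal(tb$crmse, 0, tolerance = 1e-9)
  expect_equal(tb$bias, 2, tolerance = 1e-12)
})

test_that("Taylor statistics match the defining sums on small series", {
  o <- c(1, 2, 3, 4); s <- c(1, 2, 2, 5)
  ts <- voltigrid:::taylor_from_series(s, o)
  # frozen values from the 4-point hand computation
  expect_equal(ts$sd_obs, sqrt(5) / 2, tolerance = 1e-12)
  expect_equal(ts$sd_sim, 1.5, tolerance = 1e-12)
  expect_equal(ts$r, 1.5 / (1.5 * sqrt(5) / 2), tolerance = 1e-12)
  expect_equal(ts$crmse, sqrt(0.5), tolerance = 1e-12)
  expect_equal(ts$bias, 0, tolerance = 1e-12)
  # and against the independent oracle on random draws
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(4:40, 1)
    s <- rnorm(n, 10, 3); o <- rnorm(n, 10, 2)
    a <- voltigrid:::taylor_from_series(s, o)
    b <- naive_taylor(s, o)
    for (f in names(b)) expect_equal(a[[f]], b[[f]], tolerance = 1e-9)
    # centered-RMSE law
    expect_equal(a$crmse^2,
                 a$sd_sim^2 + a$sd_obs^2 - 2 * a$sd_sim * a$sd_obs * a$r,
                 tolerance = 1e-9)
  }
})

test_that("skill score is bounded and ranking selects the best members", {
  mk <- function(member, r, sd_norm) {
    structure(list(member = member, r = r, sd_sim = sd_norm, sd_obs = 1,
                   sd_norm = sd_norm, crmse = NA, crmse_norm = NA,
                   bias = 0, n = 10), class = "taylor_stats")
  }
  perfect <- mk("p", 1, 1)
  expect_equal(skill_score(perfect), 1)
  set.seed(2)
  scores <- replicate(200, skill_score(mk("x", runif(1, -1, 1),
                                          runif(1, 0.1, 4))))
  expect_true(all(scores >= 0 & scores <= 1))
  stats <- list(mk("noisy", 0.8, 1.3), mk("p", 1, 1), mk("meh", 0.5, 0.7))
  expect_identical(rank_and_select(stats, 1), "p")
  expect_identical(rank_and_select(stats, 3), c("p", "noisy", "meh"))
  # hand-computed ordering via the score formula itself on fresh values
  s3 <- list(mk("a", 0.9, 1.1), mk("b", 0.95, 1.4), mk("c", 0.9, 1.1))
  sc <- vapply(s3, skill_score, numeric(1))
  expect_identical(rank_and_select(s3, 3),
                   c("a", "c", "b")[order(c(sc[1], sc[3], sc[2]),
                                          decreasing = TRUE)])
  # exact ties break alphabetically
  expect_identical(rank_and_select(list(mk("b", 0.9, 1.1),
                                        mk("a", 0.9, 1.1)), 2), c("a", "b"))
  expect_error(rank_and_select(stats, 0), "positive")
  expect_error(rank_and_select(stats, 9), "exceeds")
})

test_that("lower-perturbation members score higher on average", {
  good <- pseudo_gcm_spec("good", bias = 0.05, amplitude_factor = 1,
                          noise_sd = 0.2, seed_offset = 1)
  bad <- pseudo_gcm_spec("bad", bias = -1.2, amplitude_factor = 0.8,
                         noise_sd = 1.5, seed_offset = 2)
  diffs <- vapply(1:20, function(seed) {
    cfg <- coarse_config(seed = seed, years = 2000:2004)
    dem <- generate_dem(cfg)
    obs <- generate_observed_climate(cfg, dem, years = 2000:2004)
    sg <- skill_score(taylor_statistics(
      generate_gcm_member(cfg, dem, good, NULL, 2000:2004), obs))
    sb <- skill_score(taylor_statistics(
      generate_gcm_member(cfg, dem, bad, NULL, 2000:2004), obs))
    sg - sb
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("ensemble means respect weights and the member envelope", {
  cfg <- coarse_config(seed = 12)
  dem <- generate_dem(cfg)
  ms <- list(
    a = generate_gcm_member(cfg, dem, pseudo_gcm_spec("a", bias = 0,
                            seed_offset = 1), NULL, 2000:2001),
    b = generate_gcm_member(cfg, dem, pseudo_gcm_spec("b", bias = 2,
                            seed_offset = 2), NULL, 2000:2001))
  eq <- ensemble_mean(ms)
  expect_identical(eq$provenance, "ensemble")
  env_lo <- pmin(ms$a$tas, ms$b$tas); env_hi <- pmax(ms$a$tas, ms$b$tas)
  expect_true(all(eq$tas >= env_lo - 1e-12 & eq$tas <= env_hi + 1e-12))
  # identical members -> any single member; degenerate weights -> first member
  same <- ensemble_mean(list(a = ms$a, a2 = ms$a))
  expect_equal(same$tas, ms$a$tas, tolerance = 1e-12)
  w10 <- ensemble_mean(ms, ensemble_spec(c("a", "b"), weights = c(1, 0)))
  expect_equal(w10$tas, ms$a$tas, tolerance = 1e-12)
  # two constant fields at 10 and 14 degC average to 12
  c10 <- manual_grid(array(10, c(2, 2, 365)), lat = c(35, 36),
                     lon = c(117, 118), provenance = "c10")
  c14 <- manual_grid(array(14, c(2, 2, 365)), lat = c(35, 36),
                     lon = c(117, 118), provenance = "c14")
  mid <- ensemble_mean(list(c10 = c10, c14 = c14))
  expect_true(all(abs(mid$tas - 12) < 1e-12))
  # grid mismatch names the offender
  small <- manual_grid(array(10, c(2, 1, 365)), lat = c(35, 36), lon = 117,
                       provenance = "odd")
  expect_error(ensemble_mean(list(c10 = c10, odd = small)), "odd")
})

test_that("ensemble specs validate weights", {
  expect_error(ensemble_spec(c("a", "a")), "unique")
  expect_error(ensemble_spec(c("a", "b"), weights = c(0.7, 0.2)), "sum")
  expect_error(ensemble_spec(c("a", "b"), weights = c(1.5, -0.5)),
               "nonnegative")
  sk <- ensemble_spec(c("a", "b"), "skill", skill = c(a = 3, b = 1))
  expect_equal(sk$weights, c(0.75, 0.25))
})

test_that("member evaluation emits the full Taylor table", {
  cfg <- coarse_config(seed = 5, years = 2000:2004)
  dem <- generate_dem(cfg)
  obs <- generate_observed_climate(cfg, dem)
  hist <- lapply(default_members()[1:3], function(m)
    generate_gcm_member(cfg, dem, m, NULL, 2000:2004))
  tab <- evaluate_members(hist, obs, select = 2)
  expect_setequal(names(tab), c("member", "r", "sd_sim", "sd_obs", "sd_norm",
                                "crmse", "crmse_norm", "bias", "skill",
                                "selected"))
  expect_equal(sum(tab$selected), 2)
  expect_true(all(diff(tab$skill) <= 0))
  expect_error(taylor_statistics(hist[[1]], obs, years = 1900), "overlap")
})
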