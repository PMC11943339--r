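#' Pipeline run configuration
#'
#' Bundles everything an end-to-end run needs: the synthetic-climate
#' config, the scenario and member sets, the analysis resolution, the
#' baseline and future reporting windows, the projection years pooled into
#' the voltinism-versus-warming regressions, the number of members to
#' select, and the output directory.
#'
#' @param climate a [synth_config] (carries the mandatory seed).
#' @param scenarios named list of [scenario_spec]s.
#' @param members named list of [pseudo_gcm_spec]s.
#' @param analysis_resolution common analysis grid resolution in degrees.
#' @param baseline_years baseline (current-period) years.
#' @param windows named list of future reporting windows (integer year
#'   vectors), e.g. `list("2090s" = 2081:2100)`. Must not overlap.
#' @param projection_years years pooled into the regressions.
#' @param select number of members kept after skill ranking.
#' @param params a [dev_params].
#' @param weighting `"equal"` or `"skill"` ensemble weighting.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(climate,
                       scenarios = default_scenarios(),
                       members = default_members(),
                       analysis_resolution = 0.05,
                       baseline_years = climate$baseline_years,
                       windows = list("2030s" = 2021:2040,
                                      "2050s" = 2041:2060,
                                      "2070s" = 2061:2080,
                                      "2090s" = 2081:2100),
                       projection_years = 2019:2100,
                       select = 3,
                       params = dev_params(),
                       weighting = c("equal", "skill"),
                       out_dir = tempfile("voltigrid_run_")) {
  stopifnot(inherits(climate, "synth_config"))
  weighting <- match.arg(weighting)
  allw <- unlist(windows)
  if (anyDuplicated(allw)) stop("reporting windows must not overlap")
  if (is.null(climate$seed)) stop("run refused: config has no seed")
  structure(list(climate = climate, scenarios = scenarios, members = members,
                 analysis_resolution = analysis_resolution,
                 baseline_years = as.integer(baseline_years),
                 windows = windows,
                 projection_years = as.integer(projection_years),
                 select = select, params = params, weighting = weighting,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the [run_config]/[synth_config] fields; `climate.seed`
#' is mandatory and the run is refused without it. Scenario entries map
#' name to 2090s warming; member entries give bias/amplitude_factor/
#' noise_sd/seed_offset.
#'
#' @param path YAML file path.
#' @param out_dir optional override of the configured output directory.
#' @return a [run_config].
#' @export
run_config_from_yaml <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  cl <- y$climate
  if (is.null(cl$seed)) stop("run refused: 'climate.seed' missing from ", path)
  cfg <- do.call(synth_config, cl)
  scen <- if (is.null(y$scenarios)) default_scenarios() else {
    out <- lapply(names(y$scenarios),
                  function(nm) scenario_spec(nm, y$scenarios[[nm]]))
    stats::setNames(out, names(y$scenarios))
  }
  memb <- if (is.null(y$members)) default_members() else {
    out <- lapply(names(y$members), function(nm)
      do.call(pseudo_gcm_spec, c(list(name = nm), y$members[[nm]])))
    stats::setNames(out, names(y$members))
  }
  args <- list(climate = cfg, scenarios = scen, members = memb)
  for (f in c("analysis_resolution", "baseline_years", "projection_years",
              "select", "weighting"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$windows))
    args$windows <- lapply(y$windows, function(w) w[1]:w[2])
  if (!is.null(out_dir)) args$out_dir <- out_dir
  else if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  do.call(run_config, args)
}

#' Run the full projection pipeline
#'
#' Stages, in order: synthetic DEM and observed baseline; historical
#' pseudo-GCM members; Taylor evaluation and top-k selection; per-scenario
#' member generation and ensemble averaging; bilinear regridding of the
#' observed and ensemble fields to the analysis resolution; annual CGDD
#' and voltinism fields; elevation/latitude binning, period means, decadal
#' trends and voltinism-versus-warming regressions. Every stage writes its
#' artifact (NetCDF or CSV) under `config$out_dir`, and a JSON manifest
#' with parameters, seed and MD5 checksums is emitted; identical
#' config and seed give identical checksums.
#'
#' @param config a [run_config].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly (list with `artifacts`, `checksums`,
#'   `seed`, `selected`, timings).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  cl <- config$climate
  art <- character(0)
  add <- function(x, p) { art[x] <<- p; p }

  say("stage synth: DEM + observed baseline (%d-%d)",
      min(config$baseline_years), max(config$baseline_years))
  dem <- stage("synth", generate_dem(cl))
  obs <- stage("synth",
               generate_observed_climate(cl, dem, config$baseline_years))
  write_grid(obs, add("observed.nc", file.path(config$out_dir, "observed.nc")))

  say("stage evaluate: %d members, historical overlap", length(config$members))
  hist_years <- config$baseline_years[config$baseline_years <= 2014]
  hist <- stage("evaluate", lapply(config$members, function(m)
    generate_gcm_member(cl, dem, m, scenario = NULL, years = hist_years)))
  taylor <- stage("evaluate",
                  evaluate_members(hist, obs, years = hist_years,
                                   select = config$select))
  utils::write.csv(taylor, add("taylor.csv",
                               file.path(config$out_dir, "taylor.csv")),
                   row.names = FALSE)
  selected <- taylor$member[taylor$selected]
  say("stage evaluate: selected %s", paste(selected, collapse = ", "))

  espec <- if (config$weighting == "skill")
    ensemble_spec(selected, "skill",
                  skill = stats::setNames(taylor$skill, taylor$member))
  else ensemble_spec(selected, "equal")

  res <- config$analysis_resolution
  say("stage regrid: observed -> %.3g deg", res)
  obs_a <- stage("regrid", regrid_bilinear(obs, res))
  base_field <- stage("voltinism", cgdd_field(obs_a, config$params))
  binning <- gradient_binning()
  bins <- stage("gradients",
                assign_bins(base_field$elevation, base_field$lat, binning))
  utils::write.csv(
    data.frame(lat = rep(base_field$lat, length(base_field$lon)),
               lon = rep(base_field$lon, each = length(base_field$lat)),
               elevation_bin = bins$elevation_bin,
               latitude_bin = bins$latitude_bin),
    add("bins.csv", file.path(config$out_dir, "bins.csv")),
    row.names = FALSE)

  base_mean <- period_mean(base_field, config$baseline_years)
  base_t <- annual_mean_series(obs_a)

  future_years <- sort(unique(c(config$projection_years,
                                unlist(config$windows))))
  summary_rows <- list(); trend_rows <- list(); reg_rows <- list()
  base_ann <- apply(base_field$voltinism, 3, mean, na.rm = TRUE)
  base_cg_ann <- apply(base_field$cgdd, 3, mean, na.rm = TRUE)
  btr <- decadal_trend(base_cg_ann, base_field$years)
  trend_rows[[1]] <- data.frame(scope = "domain", scenario = "baseline",
                                variable = "cgdd",
                                slope_per_decade = btr$slope_per_decade,
                                ci_low = btr$ci_low, ci_high = btr$ci_high,
                                r2 = btr$r_squared)
  btrn <- decadal_trend(base_ann, base_field$years)
  trend_rows[[2]] <- data.frame(scope = "domain", scenario = "baseline",
                                variable = "voltinism",
                                slope_per_decade = btrn$slope_per_decade,
                                ci_low = btrn$ci_low, ci_high = btrn$ci_high,
                                r2 = btrn$r_squared)
  summary_rows[[1]] <- data.frame(
    scope = "domain", scenario = "baseline", period = "current",
    mean_voltinism = mean(base_ann), sd_voltinism = stats::sd(base_ann),
    mean_cgdd = mean(base_cg_ann), delta_voltinism = NA_real_,
    delta_t = NA_real_)

  for (sc_name in names(config$scenarios)) {
    sc <- config$scenarios[[sc_name]]
    say("stage ensemble: %s (%d members, %d years)", sc_name,
        length(selected), length(future_years))
    mem_grids <- stage("ensemble", lapply(config$members[selected],
      function(m) generate_gcm_member(cl, dem, m, sc, future_years)))
    ens <- stage("ensemble", ensemble_mean(mem_grids, espec))
    ens_a <- stage("regrid", regrid_bilinear(ens, res))
    rm(mem_grids, ens)
    write_grid(ens_a, add(paste0("ensemble_", sc_name, ".nc"),
                          file.path(config$out_dir,
                                    paste0("ensemble_", sc_name, ".nc"))))
    fut_field <- stage("voltinism", cgdd_field(ens_a, config$params))
    fut_t <- annual_mean_series(ens_a)

    # annual domain anomalies pooled into the warming regression
    proj <- intersect(config$projection_years, fut_field$years)
    ann_n <- apply(fut_field$voltinism, 3, mean, na.rm = TRUE)
    d_n <- ann_n[match(proj, fut_field$years)] - mean(base_ann)
    d_t <- fut_t[as.character(proj)] - mean(base_t)
    fit <- voltinism_temperature_regression(d_t, d_n)
    reg_rows[[length(reg_rows) + 1]] <- data.frame(
      bin = "domain", scenario = sc_name,
      slope_per_degC = fit$slope_per_degc, r2 = fit$r_squared, n = fit$n,
      dN_at_1C = fit$predicted[1], dN_at_1.5C = fit$predicted[2],
      dN_at_2C = fit$predicted[3])
    for (ax in c("elevation_bin", "latitude_bin")) {
      memb <- bins[[ax]]
      bser <- bin_annual_series(fut_field, memb)
      bser_base <- bin_annual_series(base_field, memb)
      for (b in levels(memb)) {
        if (all(is.na(bser[b, ]))) next
        db_n <- bser[b, match(proj, fut_field$years)] -
          mean(bser_base[b, ])
        fitb <- voltinism_temperature_regression(d_t, db_n)
        reg_rows[[length(reg_rows) + 1]] <- data.frame(
          bin = b, scenario = sc_name,
          slope_per_degC = fitb$slope_per_degc, r2 = fitb$r_squared,
          n = fitb$n, dN_at_1C = fitb$predicted[1],
          dN_at_1.5C = fitb$predicted[2], dN_at_2C = fitb$predicted[3])
      }
    }

    ftr <- decadal_trend(ann_n[match(proj, fut_field$years)], proj)
    trend_rows[[length(trend_rows) + 1]] <- data.frame(
      scope = "domain", scenario = sc_name, variable = "voltinism",
      slope_per_decade = ftr$slope_per_decade, ci_low = ftr$ci_low,
      ci_high = ftr$ci_high, r2 = ftr$r_squared)

    for (w in names(config$windows)) {
      wy <- intersect(config$windows[[w]], fut_field$years)
      if (!length(wy)) next
      wmean <- period_mean(fut_field, wy)
      dN <- delta_voltinism(wmean, base_mean)
      ann_w <- apply(fut_field$voltinism[, , fut_field$years %in% wy,
                                         drop = FALSE], 3, mean, na.rm = TRUE)
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        scope = "domain", scenario = sc_name, period = w,
        mean_voltinism = mean(ann_w), sd_voltinism = stats::sd(ann_w),
        mean_cgdd = mean(period_mean(fut_field, wy, "cgdd"), na.rm = TRUE),
        delta_voltinism = mean(dN, na.rm = TRUE),
        delta_t = mean(fut_t[as.character(wy)]) - mean(base_t))
    }
    rm(fut_field, ens_a)
  }

  utils::write.csv(do.call(rbind, trend_rows),
                   add("trends.csv", file.path(config$out_dir, "trends.csv")),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, reg_rows),
                   add("regressions.csv",
                       file.path(config$out_dir, "regressions.csv")),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, summary_rows),
                   add("summary.csv",
                       file.path(config$out_dir, "summary.csv")),
                   row.names = FALSE)

  manifest <- list(
    package = "voltigrid",
    seed = cl$seed,
    analysis_resolution = res,
    baseline_years = range(config$baseline_years),
    windows = lapply(config$windows, range),
    scenarios = lapply(config$scenarios, function(s) s$warming_2090s),
    members = names(config$members),
    selected = selected,
    weighting = config$weighting,
    params = list(t0 = config$params$t0, k = config$params$k),
    artifacts = as.list(art),
    checksums = as.list(unname(tools::md5sum(unlist(art)))),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  names(manifest$checksums) <- names(art)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline done in %.1f s; %d artifacts in %s",
      manifest$elapsed_s, length(art), config$out_dir)
  invisible(manifest)
}

#' Summarize a pipeline run
#'
#' Re-reads the stage CSVs of a finished run and assembles the reporting
#' table: one row per (scope, scenario, period) with period means, the
#' voltinism change versus baseline, and the domain warming.
#'
#' @param run a manifest from [run_pipeline], or the run's output
#'   directory.
#' @return data frame.
#' @export
report_summary <- function(run) {
  dir <- if (is.character(run)) run else
    dirname(run$artifacts[["summary.csv"]])
  s <- utils::read.csv(file.path(dir, "summary.csv"))
  tr <- utils::read.csv(file.path(dir, "trends.csv"))
  key <- paste(tr$scope, tr$scenario, tr$variable)
  s$trend_per_decade <- tr$slope_per_decade[
    match(paste(s$scope, s$scenario, "voltinism"), key)]
  s
}
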