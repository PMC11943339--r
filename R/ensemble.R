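#' Taylor statistics between a simulated and an observed grid
#'
#' Compares the domain-mean daily temperature series of two grids over their
#' common (year, day-of-year) steps, optionally restricted to a set of
#' years, and returns the pattern statistics displayed on a Taylor diagram:
#' Pearson correlation, the two standard deviations, the normalized SD
#' (sim/obs), the centered RMSE (and its obs-normalized form), and the
#' overall mean bias. Standard deviations and cRMSE use the 1/n
#' (population) convention, under which the Taylor identity
#' \eqn{cRMSE^2 = \sigma_s^2 + \sigma_o^2 - 2 \sigma_s \sigma_o r}
#' holds exactly.
#'
#' @param sim,obs [climate_grid]s on a common grid.
#' @param years optional integer years restricting the comparison period.
#' @return object of class `taylor_stats`.
#' @export
taylor_statistics <- function(sim, obs, years = NULL) {
  stopifnot(inherits(sim, "climate_grid"), inherits(obs, "climate_grid"))
  idx <- align_time(sim, obs)
  if (!is.null(years)) {
    keep <- sim$time$year[idx$i] %in% years
    idx$i <- idx$i[keep]; idx$j <- idx$j[keep]
  }
  if (length(idx$i) < 2)
    stop("fewer than 2 overlapping time steps between sim and obs")
  s <- domain_mean_series(sim)[idx$i]
  o <- domain_mean_series(obs)[idx$j]
  taylor_from_series(s, o, provenance = sim$provenance)
}

# the defining sums, on plain vectors (also the shape the oracle tests use)
taylor_from_series <- function(s, o, provenance = NA_character_) {
  n <- length(s)
  sa <- s - mean(s); oa <- o - mean(o)
  sd_sim <- sqrt(sum(sa^2) / n)
  sd_obs <- sqrt(sum(oa^2) / n)
  r <- if (sd_sim == 0 || sd_obs == 0) NA_real_ else
    sum(sa * oa) / (n * sd_sim * sd_obs)
  crmse <- sqrt(sum((sa - oa)^2) / n)
  structure(list(member = provenance, r = r, sd_sim = sd_sim,
                 sd_obs = sd_obs, sd_norm = sd_sim / sd_obs,
                 crmse = crmse, crmse_norm = crmse / sd_obs,
                 bias = mean(s) - mean(o), n = n),
            class = "taylor_stats")
}

#' @export
print.taylor_stats <- function(x, ...) {
  cat(sprintf("<taylor_stats> %s (n = %d)\n", x$member, x$n))
  cat(sprintf("  r = %.4f, sd_sim = %.3f, sd_obs = %.3f (ratio %.3f)\n",
              x$r, x$sd_sim, x$sd_obs, x$sd_norm))
  cat(sprintf("  cRMSE = %.3f (normalized %.3f), bias = %+.3f degC, skill = %.4f\n",
              x$crmse, x$crmse_norm, x$bias, skill_score(x)))
  invisible(x)
}

#' Taylor skill score
#'
#' \eqn{S = (1+r)^4 / (4 (\hat\sigma + 1/\hat\sigma)^2)} with
#' \eqn{\hat\sigma} the normalized SD. S lies in (0, 1] and equals 1 exactly
#' when r = 1 and the SDs match (equivalently, cRMSE = 0 and
#' \eqn{\sigma_{sim} = \sigma_{obs}}).
#'
#' @param stats a [taylor_statistics] result.
#' @return numeric skill in (0, 1].
#' @export
skill_score <- function(stats) {
  stopifnot(inherits(stats, "taylor_stats"))
  (1 + stats$r)^4 / (4 * (stats$sd_norm + 1 / stats$sd_norm)^2)
}

#' Rank members by skill and select the best k
#'
#' Members are ordered by decreasing Taylor skill score, ties broken
#' alphabetically by member name.
#'
#' @param stats_list list of [taylor_statistics] results, one per member.
#' @param k number of members to select.
#' @return character vector of the k selected member names, best first.
#' @export
rank_and_select <- function(stats_list, k) {
  if (k <= 0) stop("'k' must be positive")
  if (k > length(stats_list))
    stop(sprintf("k = %d exceeds the number of members (%d)", k,
                 length(stats_list)))
  nm <- vapply(stats_list, `[[`, "", "member")
  s <- vapply(stats_list, skill_score, numeric(1))
  nm[order(-s, nm)][seq_len(k)]
}

#' Ensemble averaging specification
#'
#' @param members character vector of member names.
#' @param mode `"equal"` or `"skill"` weighting.
#' @param weights optional nonnegative weights summing to 1; derived from
#'   the mode when omitted (`"skill"` requires `skill` values).
#' @param skill optional numeric skill scores named by member, used for
#'   `mode = "skill"`.
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(members, mode = c("equal", "skill"),
                          weights = NULL, skill = NULL) {
  mode <- match.arg(mode)
  members <- as.character(members)
  if (anyDuplicated(members)) stop("member names must be unique")
  if (is.null(weights)) {
    weights <- if (mode == "equal") {
      rep(1 / length(members), length(members))
    } else {
      if (is.null(skill)) stop("skill weighting needs 'skill' values")
      s <- skill[members]
      as.numeric(s / sum(s))
    }
  }
  if (length(weights) != length(members))
    stop("'weights' must match 'members' in length")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  structure(list(members = members, mode = mode, weights = weights),
            class = "ensemble_spec")
}

#' Weighted multi-model ensemble mean
#'
#' Per-cell, per-day weighted average of member grids on identical
#' grids/periods. The result's provenance is `"ensemble"`.
#'
#' @param members named list of [climate_grid]s (names matching the spec).
#' @param spec an [ensemble_spec]; default equal weights over all members.
#' @return a [climate_grid].
#' @export
ensemble_mean <- function(members, spec = NULL) {
  stopifnot(length(members) >= 1)
  if (is.null(names(members)))
    names(members) <- vapply(members, `[[`, "", "provenance")
  if (is.null(spec)) spec <- ensemble_spec(names(members))
  ref <- members[[spec$members[1]]]
  acc <- array(0, dim(ref$tas))
  for (i in seq_along(spec$members)) {
    nm <- spec$members[i]
    g <- members[[nm]]
    if (is.null(g)) stop("member '", nm, "' not found in 'members'")
    if (!isTRUE(all.equal(g$lat, ref$lat)) ||
        !isTRUE(all.equal(g$lon, ref$lon)) ||
        !identical(dim(g$tas), dim(ref$tas)) ||
        !identical(g$time, ref$time))
      stop("member '", nm, "' is not on the common grid/period")
    acc <- acc + spec$weights[i] * g$tas
  }
  climate_grid(ref$lat, ref$lon, ref$time, acc, calendar = ref$calendar,
               elevation = ref$elevation, provenance = "ensemble")
}

#' Evaluate an ensemble of members against observations
#'
#' Convenience wrapper: Taylor statistics and skill for every member over
#' the comparison years, with the top-k selection flagged. This is the table
#' behind a Taylor diagram.
#'
#' @param members named list of historical member [climate_grid]s.
#' @param obs observed [climate_grid].
#' @param years comparison years (default: full overlap).
#' @param select number of members to mark as selected (default 3).
#' @return data frame with one row per member: `member`, `r`, `sd_sim`,
#'   `sd_obs`, `sd_norm`, `crmse`, `crmse_norm`, `bias`, `skill`,
#'   `selected`.
#' @export
evaluate_members <- function(members, obs, years = NULL, select = 3) {
  stats <- lapply(members, taylor_statistics, obs = obs, years = years)
  sel <- rank_and_select(stats, min(select, length(stats)))
  df <- do.call(rbind, lapply(stats, function(s)
    data.frame(member = s$member, r = s$r, sd_sim = s$sd_sim,
               sd_obs = s$sd_obs, sd_norm = s$sd_norm, crmse = s$crmse,
               crmse_norm = s$crmse_norm, bias = s$bias,
               skill = skill_score(s))))
  df$selected <- df$member %in% sel
  rownames(df) <- NULL
  df[order(-df$skill, df$member), ]
}
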