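# Monte Carlo uncertainty: normal draws of CRF percent estimates and
# mortality-rate ratios, empirical confidence intervals pooled over draws
# and ensemble members, and the four-factor decomposition of burden change.

z975 <- 1.959964

#' Sample concentration-response coefficient draws
#'
#' One normal draw per stratum per iteration on the reported percent scale,
#' with `sd = (ci_high - ci_low) / (2 x 1.959964)`. Draws are shared across
#' cities (strata-consistent within an iteration). Negative draws are
#' retained: a CRF whose CI crosses zero legitimately contributes negative
#' attributable deaths to the uncertainty distribution.
#'
#' @param crfs CRF tibble (see [default_crf_table()]).
#' @param n_draws Number of draws (default 1000).
#' @param seed Integer seed.
#' @return Tibble `draw, stratum_type, stratum, pct`.
#' @export
sample_crf_draws <- function(crfs, n_draws = 1000, seed = 1L) {
  stopifnot(n_draws >= 1)
  with_seed_local(seed, {
    purrr::pmap_dfr(crfs[, c("stratum_type", "stratum", "pct",
                             "ci_low", "ci_high")],
      function(stratum_type, stratum, pct, ci_low, ci_high) {
        sdv <- (ci_high - ci_low) / (2 * z975)
        tibble(draw = seq_len(n_draws), stratum_type = stratum_type,
               stratum = stratum, pct = rnorm(n_draws, pct, sdv))
      })
  })
}

#' Sample mortality-rate-ratio draws
#'
#' Normal draws per age group with `sd = (pi_high - pi_low)/(2 x 1.959964)`,
#' truncated at 0 (negative rates are unphysical); the number of truncated
#' draws is recorded in attribute `"n_truncated"`.
#'
#' @param ratios Rate-ratio tibble (see [default_rate_ratios()]).
#' @param n_draws Number of draws.
#' @param seed Integer seed.
#' @return Tibble `draw, age_group, ratio`.
#' @export
sample_rate_ratio_draws <- function(ratios, n_draws = 1000, seed = 1L) {
  stopifnot(n_draws >= 1)
  with_seed_local(seed, {
    out <- purrr::pmap_dfr(ratios[, c("age_group", "ratio",
                                      "pi_low", "pi_high")],
      function(age_group, ratio, pi_low, pi_high) {
        sdv <- (pi_high - pi_low) / (2 * z975)
        tibble(draw = seq_len(n_draws), age_group = age_group,
               ratio = rnorm(n_draws, ratio, sdv))
      })
    ntrunc <- sum(out$ratio < 0)
    out$ratio <- pmax(out$ratio, 0)
    attr(out, "n_truncated") <- ntrunc
    out
  })
}

#' Empirical confidence interval of a Monte Carlo outcome
#'
#' Percentile interval (linear interpolation between order statistics,
#' quantile type 7) of the pooled distribution — by design the 3,000-value
#' pool of 1,000 coefficient draws x 3 ensemble members.
#'
#' @param values Numeric outcome values across draws x members.
#' @param level Interval level (default 0.95).
#' @return Tibble `lower, upper`.
#' @export
#' @examples
#' empirical_ci(1:1000) # ~ (25.975, 975.025)
empirical_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("need at least 2 values for an empirical CI")
  a <- (1 - level) / 2
  q <- quantile(values, c(a, 1 - a), type = 7, names = FALSE)
  tibble(lower = q[1], upper = q[2])
}

#' Ensemble mean of an outcome over members
#'
#' Unweighted mean over ensemble members at point CRFs, grouped by every
#' other identifying column.
#'
#' @param results Tibble containing a `member` column and the outcome.
#' @param value Name of the outcome column (default `"excess"`).
#' @return Tibble with `member` collapsed to the mean outcome.
#' @export
ensemble_mean <- function(results, value = "excess") {
  keys <- setdiff(names(results), c("member", value))
  results %>%
    group_by(across(dplyr::all_of(keys))) %>%
    summarise("{value}" := mean(.data[[value]]), .groups = "drop")
}

# Annualized AF-years per city for a matrix of coefficient draws.
# Returns cities x draws matrix; season strata contribute only in-season
# days while out-of-season covered days count as zeros.
af_year_matrix <- function(series, betas, season = NULL,
                           seasons = season_spec(), chunk = 250) {
  keep <- !is.na(series$value)
  C <- series$value[keep]
  city <- series$city_id[keep]
  inseason <- if (is.null(season)) rep(TRUE, length(C)) else
    season_of(series$date[keep], seasons) == season
  Cs <- C * inseason          # off-season days contribute AF at C = 0
  cities <- sort(unique(series$city_id))
  ncov <- tapply(rep(1, length(city)), factor(city, cities), sum)
  ncov[is.na(ncov)] <- 0
  out <- matrix(0, length(cities), length(betas),
                dimnames = list(cities, NULL))
  for (s in seq(1, length(betas), by = chunk)) {
    idx <- s:min(s + chunk - 1, length(betas))
    af <- 1 - exp(-outer(Cs, betas[idx]))
    out[, idx] <- rowsum(af, group = factor(city, cities))
  }
  sweep(out, 1, as.numeric(ncov) / 365.25, "/")
}

#' Monte Carlo excess-mortality draw table
#'
#' Re-evaluates the stratified assessment for every coefficient draw (and,
#' for age strata under rate-changing scenarios, every rate-ratio draw),
#' per climate scenario, ensemble member, and population scenario. The
#' resulting distribution, pooled over draws and members, is the basis of
#' the empirical confidence intervals.
#'
#' @param exposures Exposure table as in [run_stratified_assessment()].
#' @param crfs CRF tibble.
#' @param baseline Historical baseline mortality table.
#' @param pop_scenarios Output of [generate_population_scenarios()].
#' @param n_draws Number of coefficient draws (default 1000).
#' @param seed Integer seed for the draw streams.
#' @param rate_ratios Rate-ratio tibble (default from `pop_scenarios`).
#' @param seasons A [season_spec()].
#' @return Tibble `stratum_type, stratum, rcp, pop_scenario, member, draw,
#'   annual_hist, annual_future, excess` (city-summed totals).
#' @export
mc_excess_draws <- function(exposures, crfs, baseline, pop_scenarios,
                            n_draws = 1000, seed = 1L,
                            rate_ratios = NULL, seasons = season_spec()) {
  rate_ratios <- rate_ratios %||% attr(pop_scenarios, "rate_ratios") %||%
    default_rate_ratios()
  crf_draws <- sample_crf_draws(crfs, n_draws, derive_seed(seed, "crf-draws"))
  rr_draws <- sample_rate_ratio_draws(rate_ratios, n_draws,
                                      derive_seed(seed, "rate-draws"))
  rr_wide <- tidyr::pivot_wider(rr_draws, names_from = "age_group",
                                values_from = "ratio")

  hist_series <- exposures %>% filter(.data$period == "historical") %>%
    distinct(.data$city_id, .data$date, .data$value)
  combos <- exposures %>% filter(.data$period == "future") %>%
    distinct(.data$scenario, .data$member)

  purrr::pmap_dfr(crfs[, c("stratum_type", "stratum")],
    function(stratum_type, stratum) {
      pcts <- crf_draws$pct[crf_draws$stratum_type == stratum_type &
                              crf_draws$stratum == stratum]
      betas <- beta_from_percent(pmax(pcts, -99.9))
      season <- if (stratum_type == "season") stratum else NULL
      b_hist <- baseline %>%
        filter(.data$stratum_type == .env$stratum_type,
               .data$stratum == .env$stratum)
      Ah <- af_year_matrix(hist_series, betas, season, seasons)
      bh <- setNames(b_hist$mean_daily_deaths, b_hist$city_id)[rownames(Ah)]
      hist_tot <- colSums(bh * Ah)    # per-draw historical annual deaths

      purrr::pmap_dfr(combos, function(scenario, member) {
        fut <- exposures %>%
          filter(.data$period == "future", .data$scenario == .env$scenario,
                 .data$member == .env$member)
        Af <- af_year_matrix(fut, betas, season, seasons)
        bfp <- bh[rownames(Af)]
        purrr::map_dfr(seq_len(nrow(pop_scenarios)), function(i) {
          ps <- pop_scenarios[i, ]
          fac <- rep(1, n_draws)
          if (stratum_type == "age") {
            f10 <- c(`5-64` = ps$f2010_5_64, `65-74` = ps$f2010_65_74,
                     `75+` = ps$f2010_75p)[stratum]
            f50 <- c(`5-64` = ps$f2050_5_64, `65-74` = ps$f2050_65_74,
                     `75+` = ps$f2050_75p)[stratum]
            fac <- rep(ps$pop_ratio * f50 / f10, n_draws)
            if (ps$has_rate_change) fac <- fac * rr_wide[[stratum]]
          }
          fut_tot <- colSums(bfp * Af) * fac
          tibble(stratum_type = stratum_type, stratum = stratum,
                 rcp = scenario, pop_scenario = ps$scenario_id,
                 member = member, draw = seq_len(n_draws),
                 annual_hist = hist_tot, annual_future = fut_tot,
                 excess = fut_tot - hist_tot)
        })
      })
    })
}

#' Summarise a draw table into ensemble-mean estimates with empirical CIs
#'
#' Central estimates are the ensemble means of the point-CRF assessment;
#' interval bounds are the 2.5th/97.5th percentiles of the draw x member
#' pool.
#'
#' @param draw_table Output of [mc_excess_draws()].
#' @param point Optional point assessment ([run_stratified_assessment()]
#'   output, city-level) whose ensemble-mean totals become the central
#'   estimates; when NULL the draw means are used.
#' @param level Interval level (default 0.95).
#' @return Tibble `stratum_type, stratum, rcp, pop_scenario, excess,
#'   lower, upper, pct_change, annual_hist`.
#' @export
summarise_eci <- function(draw_table, point = NULL, level = 0.95) {
  pooled <- draw_table %>%
    group_by(.data$stratum_type, .data$stratum, .data$rcp,
             .data$pop_scenario) %>%
    summarise(lower = empirical_ci(.data$excess, level)$lower,
              upper = empirical_ci(.data$excess, level)$upper,
              excess_draw_mean = mean(.data$excess),
              annual_hist = mean(.data$annual_hist),
              .groups = "drop")
  if (!is.null(point)) {
    central <- point %>%
      group_by(.data$stratum_type, .data$stratum, .data$rcp,
               .data$pop_scenario, .data$member) %>%
      summarise(excess = sum(.data$excess),
                annual_hist = sum(.data$annual_hist), .groups = "drop") %>%
      ensemble_mean("excess") %>%
      group_by(.data$stratum_type, .data$stratum, .data$rcp,
               .data$pop_scenario) %>%
      summarise(excess = mean(.data$excess),
                annual_hist = first(.data$annual_hist), .groups = "drop")
    pooled <- pooled %>%
      select(-"annual_hist") %>%
      left_join(central, by = c("stratum_type", "stratum", "rcp",
                                "pop_scenario"))
  } else {
    pooled <- pooled %>% rename(excess = "excess_draw_mean")
  }
  pooled %>%
    mutate(pct_change = 100 * .data$excess / .data$annual_hist) %>%
    select("stratum_type", "stratum", "rcp", "pop_scenario",
           "excess", "lower", "upper", "pct_change", "annual_hist")
}

#' Four-factor decomposition of the change in ozone-attributable deaths
#'
#' Runs the age-stratified assessment under four nested configurations —
#' no population change; population size only; size + aging; size + aging +
#' mortality-rate change — and reports the incremental (telescoping)
#' contributions: climate/emission effect `E0`, size effect `E1 - E0`,
#' aging effect `E2 - E1`, rate effect `E3 - E2` (zero by construction for
#' scenarios without rate changes, whose ratios are 1); the four sum to the total
#' change `E3` exactly. Percent contributions are relative to historical
#' age-stratified annual attributable deaths.
#'
#' @param exposures Exposure table as in [run_stratified_assessment()].
#' @param crfs CRF tibble (only `age` strata are used, with age-specific
#'   baselines).
#' @param baseline Historical baseline mortality table.
#' @param pop_scenarios Output of [generate_population_scenarios()].
#' @param scenario_id Population scenario to decompose (e.g. `"S1"`).
#' @param rate_ratios Rate-ratio tibble (default from `pop_scenarios`).
#' @param seasons A [season_spec()].
#' @return An `oz_decomposition` tibble with one row per (rcp, member):
#'   effects in deaths/year and as percent of the historical burden.
#' @export
decompose_drivers <- function(exposures, crfs, baseline, pop_scenarios,
                              scenario_id, rate_ratios = NULL,
                              seasons = season_spec()) {
  rate_ratios <- rate_ratios %||% attr(pop_scenarios, "rate_ratios") %||%
    default_rate_ratios()
  ps <- pop_scenarios %>% filter(.data$scenario_id == .env$scenario_id)
  if (nrow(ps) != 1) abort(sprintf("unknown population scenario '%s'", scenario_id))
  age_crfs <- crfs %>% filter(.data$stratum_type == "age")
  age_base <- baseline %>% filter(.data$stratum_type == "age")

  hist_series <- exposures %>% filter(.data$period == "historical") %>%
    distinct(.data$city_id, .data$date, .data$value)
  hist_tot <- sum(assess_annual(hist_series, age_crfs, age_base,
                                seasons)$annual_attributable)

  configs <- list(
    E0 = list(scale = FALSE, aging = FALSE, rates = FALSE),
    E1 = list(scale = TRUE, aging = FALSE, rates = FALSE),
    E2 = list(scale = TRUE, aging = TRUE, rates = FALSE),
    E3 = list(scale = TRUE, aging = TRUE, rates = TRUE)
  )
  combos <- exposures %>% filter(.data$period == "future") %>%
    distinct(.data$scenario, .data$member)
  out <- purrr::pmap_dfr(combos, function(scenario, member) {
    fut <- exposures %>%
      filter(.data$period == "future", .data$scenario == .env$scenario,
             .data$member == .env$member)
    E <- purrr::map_dbl(configs, function(cf) {
      fb <- if (!cf$scale) age_base else
        scale_future_baseline(age_base, ps, rate_ratios,
                              include_aging = cf$aging,
                              include_rate_change = cf$rates &&
                                ps$has_rate_change)
      sum(assess_annual(fut, age_crfs, fb, seasons)$annual_attributable) -
        hist_tot
    })
    tibble(rcp = scenario, pop_scenario = scenario_id, member = member,
           climate_effect = E[["E0"]],
           size_effect = E[["E1"]] - E[["E0"]],
           aging_effect = E[["E2"]] - E[["E1"]],
           rate_effect = E[["E3"]] - E[["E2"]],
           total = E[["E3"]],
           annual_hist = hist_tot)
  })
  out <- out %>%
    mutate(across(c("climate_effect", "size_effect", "aging_effect",
                    "rate_effect", "total"),
                  ~ 100 * .x / .data$annual_hist,
                  .names = "{.col}_pct"))
  class(out) <- c("oz_decomposition", class(out))
  out
}
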