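# Synthetic demographic inputs: population-change scenario ladder, age
# structures, mortality-rate change ratios, and baseline mortality tables.

AGE_GROUPS <- c("5-64", "65-74", "75+")
CAUSES <- c("non-accidental", "cardiovascular", "respiratory")

#' Mortality-rate change ratios for 2050-2055 vs 2010-2015
#'
#' Per-age-group multipliers on the baseline mortality rate with 95%
#' prediction intervals: 0.68 (0.35-1.02) for ages 5-64, 0.50 (0.26-0.73)
#' for 65-74, and 0.83 (0.61-1.05) for 75+.
#'
#' @return Tibble `age_group, ratio, pi_low, pi_high`.
#' @export
default_rate_ratios <- function() {
  tibble(
    age_group = AGE_GROUPS,
    ratio = c(0.68, 0.50, 0.83),
    pi_low = c(0.35, 0.26, 0.61),
    pi_high = c(1.02, 0.73, 1.05)
  )
}

#' Population-change scenario ladder
#'
#' Six scenarios: NOCHANGE (2050 population and age structure identical to
#' 2010, rate ratios 1) plus five SSP-like scenarios with modest total-size
#' declines (0.5%-5.6%) and strong aging: the 65-74 share rises from 5.2%
#' to 11.7%-14.0% and the 75+ share from 3.0% to 12.0%-19.0%. Age structure
#' is national (uniform across cities). The remainder after the three
#' modeled groups is the under-5 share, excluded from assessment.
#'
#' @param cfg A [truth_config()] (drives city 2010 population sizes).
#' @return Tibble with one row per scenario (`scenario_id`, `pop_ratio`,
#'   2010/2050 age-group fractions, `has_rate_change`), city populations in
#'   attribute `"city_pop"` and rate ratios in attribute `"rate_ratios"`.
#' @export
generate_population_scenarios <- function(cfg) {
  f2010 <- c(`5-64` = 0.858, `65-74` = 0.052, `75+` = 0.030)
  ladder <- tibble(
    scenario_id = c("NOCHANGE", paste0("S", 1:5)),
    pop_ratio = c(1, 0.950, 0.970, 0.995, 0.944, 0.952),
    f2050_65_74 = c(f2010[["65-74"]], 0.138, 0.130, 0.117, 0.125, 0.140),
    f2050_75p = c(f2010[["75+"]], 0.190, 0.150, 0.120, 0.160, 0.185),
    has_rate_change = c(FALSE, rep(TRUE, 5))
  )
  under5_2050 <- 0.040
  scen <- ladder %>%
    mutate(
      f2010_5_64 = f2010[["5-64"]],
      f2010_65_74 = f2010[["65-74"]],
      f2010_75p = f2010[["75+"]],
      f2050_5_64 = if_else(.data$scenario_id == "NOCHANGE",
                           f2010[["5-64"]],
                           1 - under5_2050 - .data$f2050_65_74 - .data$f2050_75p)
    ) %>%
    select("scenario_id", "pop_ratio",
           "f2010_5_64", "f2010_65_74", "f2010_75p",
           "f2050_5_64", "f2050_65_74", "f2050_75p", "has_rate_change")

  cities <- city_geometry(cfg)
  pop2010 <- with_seed_local(derive_seed(cfg$seed, "population"), {
    round(stats::rlnorm(cfg$n_cities, log(1.6e6), 0.5))
  })
  city_pop <- tidyr::expand_grid(city_id = cities$city_id,
                                 scenario_id = scen$scenario_id) %>%
    left_join(tibble(city_id = cities$city_id, pop_2010 = pop2010),
              by = "city_id") %>%
    left_join(scen[, c("scenario_id", "pop_ratio")], by = "scenario_id") %>%
    mutate(pop_2050 = .data$pop_2010 * .data$pop_ratio) %>%
    select("city_id", "scenario_id", "pop_2010", "pop_2050")

  attr(scen, "city_pop") <- city_pop
  attr(scen, "rate_ratios") <- default_rate_ratios()
  scen
}

#' Baseline daily mortality table
#'
#' Per-city mean daily death counts by stratum. City all-cause levels are
#' lognormal with median 18/day (so the across-city mean is ~23/day and the
#' distribution is right-skewed, matching city-level summaries of the
#' reference network). Stratum shares are national constants chosen so the
#' construction is internally consistent: cause and age strata partition the
#' all-cause count (75+/5-64 ratio 2.6), and warm/cold season means average
#' to the annual mean.
#'
#' @param cfg A [truth_config()].
#' @return Tibble `city_id, stratum_type, stratum, mean_daily_deaths` with
#'   stratum types `cause` (non-accidental, cardiovascular, respiratory),
#'   `age` (5-64, 65-74, 75+) and `season` (warm, cold).
#' @export
generate_baseline_mortality <- function(cfg) {
  cities <- city_geometry(cfg)
  all_cause <- with_seed_local(derive_seed(cfg$seed, "mortality"), {
    stats::rlnorm(cfg$n_cities, log(18), 0.7)
  })
  shares <- tibble(
    stratum_type = c(rep("cause", 3), rep("age", 3), rep("season", 2)),
    stratum = c(CAUSES, AGE_GROUPS, "warm", "cold"),
    share = c(1, 11 / 23, 3 / 23,      # cardiovascular/respiratory shares
              5 / 23, 5 / 23, 13 / 23, # age partition; 75+/5-64 = 2.6
              42 / 41, 40 / 41)        # season means average to annual
  )
  tidyr::expand_grid(city_id = cities$city_id, shares) %>%
    left_join(tibble(city_id = cities$city_id, all_cause = all_cause),
              by = "city_id") %>%
    mutate(mean_daily_deaths = .data$all_cause * .data$share) %>%
    select("city_id", "stratum_type", "stratum", "mean_daily_deaths")
}
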