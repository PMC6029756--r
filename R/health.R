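# Attributable-fraction health impact assessment: AF = 1 - exp(-beta * C),
# ADD = baseline daily deaths x AF, annualized by dividing the covered-day
# sum by the covered period length in years.

#' Attributable fraction of daily mortality
#'
#' `AF = 1 - exp(-beta * C)`; with `beta, C >= 0` it lies in `[0, 1)`. No
#' concentration threshold is assumed: any positive exposure with a
#' positive coefficient yields a positive fraction.
#'
#' @param beta Coefficient per ppb (from [beta_from_percent()]).
#' @param C Daily city-level MDA8 ozone (ppb, non-negative); vectorized.
#' @return Attributable fraction.
#' @export
#' @examples
#' attributable_fraction(beta_from_percent(0.24), 50)
attributable_fraction <- function(beta, C) {
  if (any(C < 0, na.rm = TRUE)) abort("negative concentration")
  1 - exp(-beta * C)
}

#' Attributable daily deaths
#'
#' `ADD = baseline x AF`, where baseline is the city's mean daily death
#' count for the stratum (the product of the baseline mortality rate and
#' the population).
#'
#' @param baseline_daily_deaths Mean daily deaths (non-negative).
#' @param AF Attributable fraction.
#' @return Attributable daily deaths.
#' @export
attributable_daily_deaths <- function(baseline_daily_deaths, AF) {
  if (any(baseline_daily_deaths < 0, na.rm = TRUE)) abort("negative baseline")
  baseline_daily_deaths * AF
}

#' Annualize a daily attributable-death series
#'
#' Sums the defined (non-missing) daily values and divides by the covered
#' period length in years: `sum(ADD) / (n_covered / 365.25)`. Missing days
#' are excluded from both the sum and the coverage count, so a series with
#' gaps annualizes to the same rate as its observed days.
#'
#' @param add Numeric vector of daily attributable deaths (`NA` = missing).
#' @return Deaths per year.
#' @export
annualize <- function(add) {
  ncov <- sum(!is.na(add))
  if (ncov == 0) abort("no covered days to annualize")
  sum(add, na.rm = TRUE) / (ncov / 365.25)
}

#' Scale a baseline mortality table to the future period
#'
#' Age strata scale by the age-group population ratio
#' `(pop_2050 x frac_2050) / (pop_2010 x frac_2010)` (or by the total
#' population ratio when aging is excluded), optionally multiplied by the
#' age-group mortality-rate change ratio. Cause and season strata are never
#' rescaled: their future daily counts are held constant, as no projections
#' of cause- or season-specific rates are available.
#'
#' @param baseline Baseline table `city_id, stratum_type, stratum,
#'   mean_daily_deaths` (as from [generate_baseline_mortality()]).
#' @param scenario One row of [generate_population_scenarios()].
#' @param rate_ratios Tibble `age_group, ratio, ...`
#'   (default [default_rate_ratios()]).
#' @param include_aging Apply the age-structure shift (default TRUE); when
#'   FALSE all age strata scale by the total-population ratio only.
#' @param include_rate_change Apply mortality-rate change ratios (default:
#'   the scenario's `has_rate_change` flag).
#' @param rate_draw Optional named numeric vector (names = age groups)
#'   overriding the central rate ratios, e.g. one Monte Carlo draw.
#' @return Baseline table with future `mean_daily_deaths`.
#' @export
scale_future_baseline <- function(baseline, scenario,
                                  rate_ratios = default_rate_ratios(),
                                  include_aging = TRUE,
                                  include_rate_change = scenario$has_rate_change,
                                  rate_draw = NULL) {
  stopifnot(nrow(scenario) == 1)
  f2010 <- c(`5-64` = scenario$f2010_5_64, `65-74` = scenario$f2010_65_74,
             `75+` = scenario$f2010_75p)
  f2050 <- c(`5-64` = scenario$f2050_5_64, `65-74` = scenario$f2050_65_74,
             `75+` = scenario$f2050_75p)
  if (any(f2010 <= 0)) abort("zero historical age-group population share")
  ratio <- setNames(rate_ratios$ratio, rate_ratios$age_group)
  if (!is.null(rate_draw)) ratio[names(rate_draw)] <- rate_draw

  age_factor <- if (include_aging) {
    scenario$pop_ratio * f2050 / f2010
  } else {
    setNames(rep(scenario$pop_ratio, 3), names(f2010))
  }
  if (include_rate_change) age_factor <- age_factor * ratio[names(age_factor)]

  baseline %>%
    mutate(mean_daily_deaths = if_else(
      .data$stratum_type == "age",
      .data$mean_daily_deaths * unname(age_factor[.data$stratum]),
      .data$mean_daily_deaths
    ))
}

#' Change in annual attributable deaths
#'
#' City-level inputs are summed before the percent change is taken.
#'
#' @param future_annual,historical_annual Annual attributable deaths
#'   (vectors over cities or scalars).
#' @return Tibble `delta, pct_change`.
#' @export
excess_mortality <- function(future_annual, historical_annual) {
  f <- sum(future_annual); h <- sum(historical_annual)
  tibble(delta = f - h, pct_change = 100 * (f - h) / h)
}

# right-aligned running mean over up to `k` days, ignoring missing values;
# missing where no value is available in the window
running_mean <- function(v, k) {
  vapply(seq_along(v), function(i) {
    w <- v[max(1, i - k + 1):i]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

# Annualized attributable-fraction-years per city: for each city,
# sum(AF over covered days) / (covered days / 365.25). Multiplying by the
# stratum's constant mean daily deaths gives annual attributable deaths.
# Season strata contribute AF only on their own days; out-of-season covered
# days count as zeros (they remain part of the annual coverage).
af_year_by_city <- function(series, beta, season = NULL,
                            seasons = season_spec()) {
  af <- attributable_fraction(beta, series$value)
  if (!is.null(season)) {
    af[!is.na(af) & season_of(series$date, seasons) != season] <- 0
  }
  tibble(city_id = series$city_id, af = af) %>%
    group_by(.data$city_id) %>%
    summarise(af_year = sum(.data$af, na.rm = TRUE) /
                (sum(!is.na(.data$af)) / 365.25),
              .groups = "drop")
}

#' Annual attributable deaths per city and stratum for one exposure series
#'
#' Applies each CRF stratum to the daily city series and multiplies the
#' annualized attributable fraction by the stratum's baseline daily deaths.
#' Season-specific CRFs contribute only on days in their season.
#'
#' @param series Tibble `city_id, date, value` of daily MDA8 (ppb).
#' @param crfs CRF tibble (see [default_crf_table()]).
#' @param baseline Baseline mortality table for the same cities.
#' @param seasons A [season_spec()].
#' @param exposure_window Days in the right-aligned moving-average exposure
#'   window. The default 1 applies the same-day concentration; 4 honors a
#'   lag-0-3 exposure definition. Annual sums are nearly invariant to this
#'   choice because the window only redistributes smooth daily series.
#' @return Tibble `city_id, stratum_type, stratum, annual_attributable`.
#' @export
assess_annual <- function(series, crfs, baseline, seasons = season_spec(),
                          exposure_window = 1) {
  if (exposure_window > 1) {
    series <- series %>%
      group_by(.data$city_id) %>%
      arrange(.data$date, .by_group = TRUE) %>%
      mutate(value = running_mean(.data$value, exposure_window)) %>%
      ungroup()
  }
  purrr::pmap_dfr(crfs[, c("stratum_type", "stratum", "pct")],
    function(stratum_type, stratum, pct) {
      beta <- beta_from_percent(pct)
      season <- if (stratum_type == "season") stratum else NULL
      af_year_by_city(series, beta, season, seasons) %>%
        mutate(stratum_type = stratum_type, stratum = stratum)
    }) %>%
    inner_join(baseline, by = c("city_id", "stratum_type", "stratum")) %>%
    mutate(annual_attributable = .data$mean_daily_deaths * .data$af_year) %>%
    select("city_id", "stratum_type", "stratum", "annual_attributable")
}

#' Stratified assessment across climate scenarios, members and the
#' population-scenario ladder
#'
#' Produces, per ensemble member and climate scenario, annual attributable
#' deaths and their change versus the historical period for every stratum
#' (three causes, three age groups, two seasons), crossed with every
#' population scenario. Cause and season strata keep constant future
#' baseline counts; age strata scale with population size, age structure,
#' and (for scenarios that carry them) mortality-rate change ratios.
#' Age-group totals and the all-age total are reported separately; they
#' legitimately differ.
#'
#' @param exposures Tibble `city_id, date, value, period, scenario, member`;
#'   historical rows have `scenario = NA, member = NA`.
#' @param crfs CRF tibble.
#' @param baseline Historical baseline mortality table.
#' @param pop_scenarios Output of [generate_population_scenarios()].
#' @param rate_ratios Rate-ratio tibble (default from `pop_scenarios`
#'   attribute, falling back to [default_rate_ratios()]).
#' @param seasons A [season_spec()].
#' @return An `oz_assessment` tibble `city_id, stratum_type, stratum, rcp,
#'   pop_scenario, member, annual_hist, annual_future, excess`.
#' @export
run_stratified_assessment <- function(exposures, crfs, baseline,
                                      pop_scenarios,
                                      rate_ratios = NULL,
                                      seasons = season_spec()) {
  rate_ratios <- rate_ratios %||% attr(pop_scenarios, "rate_ratios") %||%
    default_rate_ratios()
  hist_series <- exposures %>% filter(.data$period == "historical") %>%
    distinct(.data$city_id, .data$date, .data$value)
  hist_annual <- assess_annual(hist_series, crfs, baseline, seasons) %>%
    rename(annual_hist = "annual_attributable")

  combos <- exposures %>%
    filter(.data$period == "future") %>%
    distinct(.data$scenario, .data$member)
  out <- purrr::pmap_dfr(combos, function(scenario, member) {
    fut_series <- exposures %>%
      filter(.data$period == "future", .data$scenario == .env$scenario,
             .data$member == .env$member)
    purrr::map_dfr(seq_len(nrow(pop_scenarios)), function(i) {
      ps <- pop_scenarios[i, ]
      fut_baseline <- scale_future_baseline(baseline, ps, rate_ratios)
      assess_annual(fut_series, crfs, fut_baseline, seasons) %>%
        rename(annual_future = "annual_attributable") %>%
        mutate(rcp = scenario, pop_scenario = ps$scenario_id, member = member)
    })
  })
  res <- out %>%
    inner_join(hist_annual, by = c("city_id", "stratum_type", "stratum")) %>%
    mutate(excess = .data$annual_future - .data$annual_hist) %>%
    select("city_id", "stratum_type", "stratum", "rcp", "pop_scenario",
           "member", "annual_hist", "annual_future", "excess")
  class(res) <- c("oz_assessment", class(res))
  res
}
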