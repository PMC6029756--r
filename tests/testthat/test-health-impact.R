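test_that("CRF percent-to-beta conversion follows the log-linear convention", {
  expect_equal(beta_from_percent(0), 0)
  expect_equal(beta_from_percent(0.24), log(1.0024) / 5)
  # 75+ vs 5-64 coefficient ratio ~ 3.2
  expect_equal(beta_from_percent(0.42) / beta_from_percent(0.13),
               log(1.0042) / log(1.0013), tolerance = 1e-12)
  expect_lt(abs(beta_from_percent(0.42) / beta_from_percent(0.13) - 3.23),
            0.01)
  expect_error(beta_from_percent(-100), "exceed")
})

test_that("attributable fraction evaluates, stays in [0,1) and is no-threshold", {
  expect_equal(attributable_fraction(0.01, 0), 0)
  expect_equal(attributable_fraction(0, 50), 0)
  b24 <- beta_from_percent(0.24)
  expect_equal(attributable_fraction(b24, 50), 1 - exp(-log(1.0024) * 10))
  expect_error(attributable_fraction(b24, -5), "negative")
  # bounds and no-threshold over the CRF table
  crfs <- default_crf_table()
  for (pct in crfs$pct) {
    b <- beta_from_percent(pct)
    af <- attributable_fraction(b, seq(0.5, 150, by = 0.5))
    expect_true(all(af > 0 & af < 1))
    expect_true(all(diff(af) > 0))  # monotone in concentration
  }
})

test_that("AF linearization error is second order for all table CRFs", {
  crfs <- default_crf_table()
  C <- seq(0, 100, by = 1)
  for (pct in crfs$pct) {
    b <- abs(beta_from_percent(pct))
    err <- abs(attributable_fraction(b, C) - b * C)
    expect_true(all(err <= (b * C)^2 / 2 + 1e-15))
  }
})

test_that("attributable daily deaths and annualization follow the stated rules", {
  expect_equal(attributable_daily_deaths(23, 0.02), 0.46)
  expect_equal(attributable_daily_deaths(0, 0.5), 0)
  expect_equal(attributable_daily_deaths(10, 0), 0)
  expect_error(attributable_daily_deaths(-1, 0.1), "negative")

  expect_equal(annualize(rep(2, 918)), 365.25 * 2)
  half <- c(rep(2, 459), rep(NA, 459))
  expect_equal(annualize(half), 365.25 * 2)
  expect_error(annualize(rep(NA_real_, 10)), "covered")
  set.seed(3)
  x <- runif(500); x[sample(500, 50)] <- NA
  expect_equal(annualize(x), sum(x, na.rm = TRUE) / (450 / 365.25))
})

test_that("future baseline scaling applies size, aging and rate factors to age strata only", {
  cfg <- tiny_cfg()
  bl <- generate_baseline_mortality(cfg)
  pop <- generate_population_scenarios(cfg)
  rr <- attr(pop, "rate_ratios")

  nc <- pop[pop$scenario_id == "NOCHANGE", ]
  expect_equal(scale_future_baseline(bl, nc, rr), bl)

  s1 <- pop[pop$scenario_id == "S1", ]
  # size-only: every age stratum scales by the total population ratio
  sized <- scale_future_baseline(bl, s1, rr, include_aging = FALSE,
                                 include_rate_change = FALSE)
  age <- bl$stratum_type == "age"
  expect_equal(sized$mean_daily_deaths[age],
               bl$mean_daily_deaths[age] * s1$pop_ratio)
  expect_equal(sized$mean_daily_deaths[!age], bl$mean_daily_deaths[!age])

  # full scenario against a hand computation on one city
  full <- scale_future_baseline(bl, s1, rr)
  one <- bl$city_id == bl$city_id[1] & bl$stratum_type == "age" &
    bl$stratum == "65-74"
  hand <- bl$mean_daily_deaths[one] *
    (s1$pop_ratio * s1$f2050_65_74 / s1$f2010_65_74) *
    rr$ratio[rr$age_group == "65-74"]
  expect_equal(full$mean_daily_deaths[one], hand)
  # cause and season strata never rescale
  expect_equal(full$mean_daily_deaths[!age], bl$mean_daily_deaths[!age])
})

test_that("excess mortality sums cities before taking percent change", {
  expect_equal(excess_mortality(100, 100), tibble::tibble(delta = 0, pct_change = 0))
  expect_equal(excess_mortality(110, 100),
               tibble::tibble(delta = 10, pct_change = 10))
  f <- c(60, 80); h <- c(40, 40)
  expect_equal(excess_mortality(f, h)$delta, 60)
  expect_equal(excess_mortality(f, h)$pct_change, 100 * 60 / 80)
})

test_that("single-stratum assessment equals the chained elementary operations", {
  s <- flat_series(value = 48, n_days = 365)
  crf <- default_crf_table()[1, ]   # all non-accidental
  bl <- tibble::tibble(city_id = "C01", stratum_type = "cause",
                       stratum = "non-accidental", mean_daily_deaths = 23)
  got <- assess_annual(s, crf, bl)$annual_attributable
  beta <- beta_from_percent(crf$pct)
  add <- attributable_daily_deaths(23, attributable_fraction(beta, rep(48, 365)))
  expect_equal(got, annualize(add))
})

test_that("the lag-window exposure option barely moves annual totals", {
  crf <- default_crf_table()[1, ]
  bl <- tibble::tibble(city_id = "C01", stratum_type = "cause",
                       stratum = "non-accidental", mean_daily_deaths = 23)
  # constant series: window choice is irrelevant
  s <- flat_series(value = 55, n_days = 200)
  expect_equal(assess_annual(s, crf, bl, exposure_window = 4),
               assess_annual(s, crf, bl))
  # smooth seasonal series: totals nearly invariant to the 4-day window
  dates <- seq(as.Date("2013-01-01"), as.Date("2013-12-31"), by = "day")
  s2 <- tibble::tibble(city_id = "C01", date = dates,
                       value = 50 + 15 * sin(2 * pi * seq_along(dates) / 365))
  a1 <- assess_annual(s2, crf, bl)$annual_attributable
  a4 <- assess_annual(s2, crf, bl, exposure_window = 4)$annual_attributable
  expect_lt(abs(a4 / a1 - 1), 0.005)
})

test_that("all-zero exposure attributes zero deaths everywhere", {
  cfg <- tiny_cfg()
  pop <- generate_population_scenarios(cfg)
  bl <- generate_baseline_mortality(cfg)
  dates <- seq(as.Date("2013-06-01"), by = "day", length.out = 60)
  zero <- tidyr::expand_grid(city_id = sprintf("C%02d", 1:4), date = dates)
  zero$value <- 0
  expos <- dplyr::bind_rows(
    dplyr::mutate(zero, period = "historical", scenario = NA_character_,
                  member = NA_integer_),
    dplyr::mutate(zero, period = "future", scenario = "high", member = 1L)
  )
  res <- run_stratified_assessment(expos, default_crf_table(), bl, pop)
  expect_equal(res$annual_hist, rep(0, nrow(res)))
  expect_equal(res$annual_future, rep(0, nrow(res)))
  expect_equal(res$excess, rep(0, nrow(res)))
})

test_that("season-specific CRFs contribute only in their own season", {
  dates <- seq(as.Date("2013-01-01"), as.Date("2013-12-31"), by = "day")
  # exposure only on cold days
  s <- tibble::tibble(city_id = "C01", date = dates,
                      value = ifelse(season_of(dates) == "cold", 60, 0))
  crfs <- default_crf_table()[default_crf_table()$stratum_type == "season", ]
  bl <- tibble::tibble(city_id = "C01",
                       stratum_type = "season", stratum = c("warm", "cold"),
                       mean_daily_deaths = c(21, 20))
  res <- assess_annual(s, crfs, bl)
  expect_equal(res$annual_attributable[res$stratum == "warm"], 0)
  expect_gt(res$annual_attributable[res$stratum == "cold"], 0)
})

test_that("age-summed results equal the all-age result when CRFs and rates coincide", {
  cfg <- tiny_cfg()
  bl <- generate_baseline_mortality(cfg)
  dates <- seq(as.Date("2013-05-01"), by = "day", length.out = 120)
  set.seed(31)
  s <- tidyr::expand_grid(city_id = sprintf("C%02d", 1:4), date = dates)
  s$value <- runif(nrow(s), 20, 90)
  shared <- tibble::tibble(
    stratum_type = c("cause", rep("age", 3)),
    stratum = c("non-accidental", "5-64", "65-74", "75+"),
    pct = 0.24, ci_low = 0.13, ci_high = 0.35
  )
  res <- assess_annual(s, shared, bl)
  by_city <- tidyr::pivot_wider(res, names_from = c("stratum_type", "stratum"),
                                values_from = "annual_attributable")
  expect_equal(by_city$`age_5-64` + by_city$`age_65-74` + by_city$`age_75+`,
               by_city$`cause_non-accidental`, tolerance = 1e-12)
})

test_that("annual attributable deaths are monotone in daily concentrations", {
  s <- flat_series(value = 40, n_days = 100)
  crf <- default_crf_table()[1, ]
  bl <- tibble::tibble(city_id = "C01", stratum_type = "cause",
                       stratum = "non-accidental", mean_daily_deaths = 23)
  base <- assess_annual(s, crf, bl)$annual_attributable
  for (i in c(1, 50, 100)) {
    s2 <- s; s2$value[i] <- s2$value[i] + 25
    expect_gt(assess_annual(s2, crf, bl)$annual_attributable, base)
  }
})
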