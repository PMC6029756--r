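# independent MDA8 oracle: explicit loop over all 17 windows
mda8_oracle <- function(v, thr = 0.75) {
  if (sum(!is.na(v)) < ceiling(24 * thr)) return(NA_real_)
  best <- -Inf
  for (s in 1:17) {
    w <- v[s:(s + 7)]
    if (sum(!is.na(w)) >= 6) best <- max(best, mean(w, na.rm = TRUE))
  }
  if (is.finite(best)) best else NA_real_
}

test_that("MDA8 follows the 8-hour window and completeness rules", {
  expect_equal(mda8_from_hourly(rep(60, 24)), 60)
  expect_equal(mda8_from_hourly(0:23), 19.5)     # hours 16..23
  # 17 valid hours: below the 75% (>=18h) day rule
  v <- c(rep(NA, 7), rep(50, 17))
  expect_true(is.na(mda8_from_hourly(v)))
  v18 <- c(rep(NA, 6), rep(50, 18))
  expect_equal(mda8_from_hourly(v18), 50)
  expect_error(mda8_from_hourly(c(-1, rep(10, 23))), "negative")
  expect_true(is.na(mda8_from_hourly(rep(NA_real_, 24))))

  # randomized patterns against the brute-force oracle
  set.seed(99)
  for (i in 1:50) {
    v <- runif(24, 0, 120)
    v[sample(24, sample(0:12, 1))] <- NA
    expect_equal(mda8_from_hourly(v), mda8_oracle(v))
  }
})

test_that("MDA8 dominates the 24-hour mean on complete days", {
  set.seed(7)
  for (i in 1:25) {
    v <- runif(24, 0, 100)
    expect_gte(mda8_from_hourly(v), mean(v))
  }
})

test_that("day counting follows Gregorian rules", {
  expect_equal(count_days_in_period("2013-04-27", "2015-10-31"), 918)
  expect_equal(count_days_in_period("2020-05-05", "2020-05-05"), 1)
  expect_equal(count_days_in_period("2014-01-01", "2014-12-31"), 365)
  expect_equal(count_days_in_period("2016-01-01", "2016-12-31"), 366)
  expect_error(count_days_in_period("2015-01-01", "2014-01-01"), "precedes")
})

test_that("mass-to-mixing-ratio conversion uses 2.0 ug/m3 per ppb", {
  expect_equal(convert_ugm3_to_ppb(100), 50)
  expect_equal(convert_ugm3_to_ppb(0), 0)
  expect_equal(convert_ugm3_to_ppb(10), 5)
  expect_error(convert_ugm3_to_ppb(-1), "negative")
})

test_that("site gridding averages sites per cell and rejects outside sites", {
  g <- grid_spec(0, 0, 1, 1, 2, 2)
  d <- as.Date("2020-01-01")
  sites <- tibble::tibble(
    site_id = c("a", "b", "c"),
    lat = c(0.2, 0.7, 1.5), lon = c(0.3, 0.4, 1.5),
    date = d, mda8 = c(40, 60, 80)
  )
  fld <- grid_site_daily(sites, g)
  expect_equal(fld$value[fld$cell_id == "r01c01"], 50)
  expect_equal(fld$value[fld$cell_id == "r02c02"], 80)
  expect_equal(nrow(fld), 2)  # cells without sites are absent (missing)
  sites$lat[1] <- 99
  expect_error(grid_site_daily(sites, g), "outside")
})

test_that("site gridding matches brute-force per-cell means on a random layout", {
  g <- grid_spec(0, 0, 1, 1, 3, 3)
  set.seed(4)
  n <- 60
  sites <- tibble::tibble(
    site_id = sprintf("s%02d", 1:n),
    lat = runif(n, 0, 3), lon = runif(n, 0, 3),
    date = as.Date("2020-06-01"), mda8 = runif(n, 20, 90)
  )
  fld <- grid_site_daily(sites, g)
  for (k in seq_len(nrow(fld))) {
    inside <- grid_locate(g, sites$lat, sites$lon) == fld$cell_id[k]
    expect_equal(fld$value[k], mean(sites$mda8[inside]))
  }
})

test_that("fine-to-coarse aggregation means the nested non-missing cells", {
  coarse <- grid_spec(0, 0, 2, 2, 1, 1)
  fine <- grid_spec(0, 0, 1, 1, 2, 2)
  d <- as.Date("2020-01-01")
  mk <- function(v) ozonehia:::new_grid_field(
    tibble::tibble(cell_id = grid_cells(fine)$cell_id, date = d, value = v),
    fine)
  expect_equal(aggregate_fine_to_coarse(mk(rep(7, 4)), coarse)$value, 7)
  expect_equal(aggregate_fine_to_coarse(mk(c(7, NA, 7, NA)), coarse)$value, 7)
  set.seed(1)
  v <- runif(4, 0, 100)
  expect_equal(aggregate_fine_to_coarse(mk(v), coarse)$value, mean(v))
})

test_that("monthly climatology averages per calendar month and fills gaps", {
  g <- grid_spec(0, 0, 1, 1, 1, 3)
  dates <- seq(as.Date("2020-01-01"), as.Date("2020-02-29"), by = "day")
  cells <- grid_cells(g)$cell_id
  df <- tidyr::expand_grid(cell_id = cells, date = dates)
  df$value <- 30
  # hand-computable January mean in one cell
  jan <- lubridate::month(df$date) == 1 & df$cell_id == "r01c01"
  df$value[jan] <- seq_len(sum(jan))
  # one cell entirely missing -> nearest-neighbour fill
  df$value[df$cell_id == "r01c03"] <- NA
  fld <- ozonehia:::new_grid_field(df, g)
  clim <- monthly_climatology(fld)
  expect_equal(clim$value[clim$cell_id == "r01c01" & clim$month == 1],
               mean(seq_len(sum(jan))))
  expect_equal(clim$value[clim$cell_id == "r01c02" & clim$month == 2], 30)
  filled <- clim[clim$cell_id == "r01c03", ]
  expect_true(all(filled$filled))
  expect_equal(filled$value[filled$month == 2], 30)  # nearest = r01c02
  expect_false(any(clim$filled[clim$cell_id != "r01c03"]))
})

test_that("city series renormalizes weights over non-missing member cells", {
  g <- grid_spec(0, 0, 1, 1, 1, 2)
  d <- as.Date("2020-01-01") + 0:2
  fld <- ozonehia:::new_grid_field(
    tidyr::expand_grid(cell_id = c("r01c01", "r01c02"), date = d) |>
      dplyr::mutate(value = dplyr::case_when(
        date == d[2] & cell_id == "r01c01" ~ NA_real_,
        date == d[3] ~ NA_real_,
        cell_id == "r01c01" ~ 40, TRUE ~ 60)), g)
  w <- tibble::tibble(city_id = "X", cell_id = c("r01c01", "r01c02"),
                      weight = c(0.25, 0.75))
  s <- city_series_from_grid(fld, w)
  expect_equal(s$value[s$date == d[1]], 0.25 * 40 + 0.75 * 60) # 55
  expect_equal(s$value[s$date == d[2]], 60)                    # renormalized
  expect_true(is.na(s$value[s$date == d[3]]))                  # all missing
  # single-cell city passes the cell value through
  w1 <- tibble::tibble(city_id = "Y", cell_id = "r01c01", weight = 1)
  expect_equal(city_series_from_grid(fld, w1)$value[1], 40)
})

test_that("station-average city series means the city's sites per day", {
  d <- as.Date("2020-01-01") + 0:1
  sd_tab <- tidyr::expand_grid(site_id = c("a", "b", "c"), date = d)
  sd_tab$mda8 <- c(40, 40, 60, 60, 80, NA)
  map <- tibble::tibble(site_id = c("a", "b", "c"),
                        city_id = c("X", "X", NA))
  s <- city_series_from_sites(sd_tab, map)
  expect_equal(nrow(s), 2)           # only city X; NA-city site ignored
  expect_equal(s$value[s$date == d[1]], 50)
  expect_equal(s$value[s$date == d[2]], 50)
})

test_that("exceedance fraction counts strictly-above days and is monotone", {
  s <- tibble::tibble(city_id = "a", date = as.Date("2020-01-01") + 0:9,
                      value = c(rep(40, 10)))
  expect_equal(exceedance_fraction(s)$exceedance, 0)
  s$value <- rep(60, 10)
  expect_equal(exceedance_fraction(s)$exceedance, 1)
  set.seed(2)
  s$value <- runif(10, 0, 100)
  expect_equal(exceedance_fraction(s, 50)$exceedance, mean(s$value > 50))
  # monotone non-increasing in the threshold
  th <- seq(0, 100, by = 10)
  fr <- vapply(th, function(t) exceedance_fraction(s, t)$exceedance, 1)
  expect_true(all(diff(fr) <= 0))
})

test_that("period means respect the seasonal partition", {
  dates <- seq(as.Date("2020-01-01"), as.Date("2020-12-31"), by = "day")
  s <- tibble::tibble(city_id = "a", date = dates, value = 33)
  expect_equal(period_mean(s, "year")$mean_ppb, 33)
  warm_only <- s
  warm_only$value <- ifelse(season_of(dates) == "warm", 50, 0)
  expect_equal(period_mean(warm_only, "cold")$mean_ppb, 0)
  expect_equal(period_mean(warm_only, "warm")$mean_ppb, 50)
  # brute-force whole-series mean with missing days excluded
  s$value[sample(366, 40)] <- NA
  expect_equal(period_mean(s, "year")$mean_ppb, mean(s$value, na.rm = TRUE))
})
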