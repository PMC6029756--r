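# helpers to build small coarse fields with controlled distributions
mk_field <- function(grid, dates, value_fun) {
  cells <- grid_cells(grid)
  df <- tidyr::expand_grid(cell_id = cells$cell_id, date = dates)
  df <- dplyr::left_join(df, cells[, c("cell_id", "lat", "lon")], by = "cell_id")
  df$value <- value_fun(df)
  ozonehia:::new_grid_field(df[, c("cell_id", "date", "value")], grid)
}

g2 <- grid_spec(0, 0, 2, 2.5, 2, 2)
dates_yr <- seq(as.Date("2013-01-01"), as.Date("2013-12-31"), by = "day")

test_that("quantile bias maps recover identity, shift and heteroscedastic bias", {
  set.seed(10)
  obs <- mk_field(g2, dates_yr, function(d) runif(nrow(d), 20, 80))
  K <- 19
  # identity
  m0 <- fit_monthly_quantile_bias(obs, obs, K = K)
  expect_equal(m0$bias, rep(0, nrow(m0)))
  expect_equal(m0$q, rep(seq_len(K) / (K + 1), nrow(m0) / K))
  # uniform +17 shift moves every quantile equally
  shifted <- obs; shifted$value <- shifted$value + 17
  m17 <- fit_monthly_quantile_bias(shifted, obs, K = K)
  expect_equal(m17$bias, rep(17, nrow(m17)), tolerance = 1e-9)
  # heteroscedastic pair against a first-principles type-7 quantile oracle
  model <- obs; model$value <- obs$value * 1.5 + 4
  mh <- fit_monthly_quantile_bias(model, obs, K = K)
  one <- mh[mh$cell_id == "r01c02" & mh$month == 7, ]
  mpool <- model$value[model$cell_id == "r01c02" &
                         lubridate::month(model$date) == 7]
  opool <- obs$value[obs$cell_id == "r01c02" &
                       lubridate::month(obs$date) == 7]
  want <- vapply(one$q, function(p) manual_quantile7(mpool, p) -
                   manual_quantile7(opool, p), 1)
  expect_equal(one$bias, want, tolerance = 1e-10)
})

test_that("bias correction inverts constant bias and is monotone", {
  set.seed(11)
  obs <- mk_field(g2, dates_yr, function(d) runif(nrow(d), 20, 80))
  m0 <- fit_monthly_quantile_bias(obs, obs, K = 19)
  expect_equal(bias_correct_daily(obs, m0)$value,
               dplyr::arrange(tibble::as_tibble(obs), cell_id, date)$value,
               tolerance = 1e-9)

  shifted <- obs; shifted$value <- obs$value + 17
  m17 <- fit_monthly_quantile_bias(shifted, obs, K = 19)
  corr <- bias_correct_daily(shifted, m17)
  want <- dplyr::arrange(tibble::as_tibble(obs), cell_id, date)
  expect_equal(corr$value, want$value, tolerance = 1e-9)

  # monotone non-decreasing within a cell-month, heteroscedastic maps
  model <- obs; model$value <- obs$value * 1.5 + 4
  mh <- fit_monthly_quantile_bias(model, obs, K = 19)
  probe <- mk_field(g2, as.Date("2013-07-10") + 0:0, function(d) 0)
  xs <- seq(0, 150, by = 0.5)
  cell_map <- mh[mh$cell_id == "r01c01" & mh$month == 7, ]
  one_day <- mk_field(g2, rep(as.Date("2013-07-10"), 1), function(d) 0)
  outs <- vapply(xs, function(x) {
    f <- one_day; f$value <- x
    bias_correct_daily(f, mh)$value[1]
  }, 1)
  expect_true(all(diff(outs) >= -1e-9))
})

test_that("correcting the historical field by its own maps hits the observed quantiles", {
  set.seed(12)
  obs <- mk_field(g2, dates_yr, function(d)
    60 + 15 * sin(2 * pi * lubridate::yday(d$date) / 365) + rnorm(nrow(d), 0, 8))
  obs$value <- pmax(obs$value, 0)
  model <- obs
  model$value <- obs$value * 1.3 + 10   # multiplicative + additive distortion
  K <- 19
  maps <- fit_monthly_quantile_bias(model, obs, K = K)
  corr <- bias_correct_daily(model, maps)
  qgrid <- seq_len(K) / (K + 1)
  for (cell in c("r01c01", "r02c02")) {
    for (mo in c(3, 8)) {
      cpool <- corr$value[corr$cell_id == cell &
                            lubridate::month(corr$date) == mo]
      opool <- obs$value[obs$cell_id == cell &
                           lubridate::month(obs$date) == mo]
      qc <- unname(quantile(cpool, qgrid, type = 7))
      qo <- unname(quantile(opool, qgrid, type = 7))
      # within interpolation tolerance of the pooled spacing
      expect_lt(max(abs(qc - qo)), 0.06 * diff(range(opool)))
    }
  }
})

test_that("a uniform future shift is preserved under constant quantile bias", {
  set.seed(13)
  obs <- mk_field(g2, dates_yr, function(d) runif(nrow(d), 30, 70))
  model <- obs; model$value <- obs$value + 17
  maps <- fit_monthly_quantile_bias(model, obs, K = 19)
  fut <- model; fut$value <- model$value + 9.5
  corr_h <- bias_correct_daily(model, maps)
  corr_f <- bias_correct_daily(fut, maps)
  expect_equal(corr_f$value - corr_h$value, rep(9.5, nrow(corr_f)),
               tolerance = 1e-9)
})

test_that("spatial disaggregation handles uniform, zero-anomaly and linear cases", {
  fine <- grid_spec(0, 0, 0.5, 0.5, 8, 10)
  d <- as.Date("2013-07-01") + 0:1
  clim_c <- tidyr::expand_grid(cell_id = grid_cells(g2)$cell_id, month = 7)
  clim_f <- tidyr::expand_grid(cell_id = grid_cells(fine)$cell_id, month = 7)

  # uniform everything -> fine field equals the coarse value
  cc <- clim_c; cc$value <- 40; cc$filled <- FALSE
  ff <- clim_f; ff$value <- 40; ff$filled <- FALSE
  corrected <- mk_field(g2, d, function(x) 55)
  out <- spatial_disaggregate_daily(
    corrected, ozonehia:::new_grid_field(cc, g2),
    ozonehia:::new_grid_field(ff, fine))
  expect_equal(out$value, rep(55, nrow(out)))

  # corrected == coarse climatology -> output equals fine climatology
  cells_f <- grid_cells(fine)
  ff2 <- clim_f
  ff2$value <- 30 + cells_f$lat[match(ff2$cell_id, cells_f$cell_id)]
  ff2$filled <- FALSE
  corrected2 <- mk_field(g2, d, function(x) 40)
  out2 <- spatial_disaggregate_daily(
    corrected2, ozonehia:::new_grid_field(cc, g2),
    ozonehia:::new_grid_field(ff2, fine))
  want2 <- ff2$value[match(out2$cell_id, ff2$cell_id)]
  expect_equal(out2$value, want2, tolerance = 1e-12)

  # linear-in-longitude anomaly interpolates to the exact plane inside the
  # coarse-center hull and clamps beyond it
  corrected3 <- mk_field(g2, d, function(x) 40 + 2 * x$lon)
  out3 <- spatial_disaggregate_daily(
    corrected3, ozonehia:::new_grid_field(cc, g2),
    ozonehia:::new_grid_field(ff, fine))
  lon_f <- cells_f$lon[match(out3$cell_id, cells_f$cell_id)]
  clon <- range(grid_cells(g2)$lon)
  want3 <- 40 + 2 * pmin(pmax(lon_f, clon[1]), clon[2])
  expect_equal(out3$value, want3, tolerance = 1e-12)
})

test_that("the full BCSD chain is a near-identity in the perfect-model limit", {
  cfg <- tiny_cfg(bias_profile = 0, member_noise_sd = 0,
                  missing_rate = 0, hour_missing_rate = 0)
  truth_c <- truth_grid_field(cfg, "coarse", "historical")
  truth_f <- truth_grid_field(cfg, "fine", "historical")
  clim_c <- monthly_climatology(truth_c)
  clim_f <- monthly_climatology(truth_f)
  suppressWarnings(
    ds <- downscale(truth_c, truth_c, truth_c, clim_c, clim_f, K = 19))
  expect_lt(abs(ds$diagnostics$pre_mean_bias), 1e-9)
  expect_lt(abs(ds$diagnostics$post_mean_bias), 0.05)
  # downscaled field reproduces the pointwise truth up to interpolation error
  j <- dplyr::inner_join(tibble::as_tibble(ds$hist_fine),
                         tibble::as_tibble(truth_f),
                         by = c("cell_id", "date"), suffix = c("", "_truth"))
  expect_lt(sqrt(mean((j$value - j$value_truth)^2)), 0.5)
  expect_lt(max(abs(j$value - j$value_truth)), 2)
})

test_that("downscaling recovers the injected trend and closes city means", {
  cfg <- tiny_cfg(seed = 21)
  obs <- generate_site_hourly_obs(cfg)
  sd_tab <- site_daily_mda8(obs)
  obs_c <- grid_site_daily(sd_tab, cfg$coarse_grid)
  obs_f <- grid_site_daily(sd_tab, cfg$fine_grid)
  clim_c <- monthly_climatology(obs_c)
  clim_f <- monthly_climatology(obs_f)
  mh <- generate_coarse_model_daily(cfg, "high", 1, "historical")
  mf <- generate_coarse_model_daily(cfg, "high", 1, "future")
  suppressWarnings(
    ds <- downscale(mh, mf, obs_c, clim_c, clim_f, K = 19))

  # diagnostics see the configured +17 ppb model bias
  expect_lt(abs(ds$diagnostics$pre_mean_bias - 17), 1.5)
  expect_lt(abs(ds$diagnostics$post_mean_bias), 0.5)

  # historical corrected city series closes on the observed city series
  w <- generate_city_geometry_weights(cfg)
  city_obs <- city_series_from_grid(obs_f, w)
  city_ds <- city_series_from_grid(ds$hist_fine, w)
  m_obs <- tapply(city_obs$value, city_obs$city_id, mean, na.rm = TRUE)
  m_ds <- tapply(city_ds$value, city_ds$city_id, mean, na.rm = TRUE)
  expect_lt(max(abs(m_obs - m_ds)), 1)

  # future city series carries the injected seasonal trend vs historical
  city_fut <- city_series_from_grid(ds$fut_fine, w)
  seas <- season_of(city_fut$date)
  d_warm <- mean(city_fut$value[seas == "warm"], na.rm = TRUE) -
    mean(city_ds$value[season_of(city_ds$date) == "warm"], na.rm = TRUE)
  d_cold <- mean(city_fut$value[seas == "cold"], na.rm = TRUE) -
    mean(city_ds$value[season_of(city_ds$date) == "cold"], na.rm = TRUE)
  expect_lt(abs(d_warm - cfg$trend_profile$high[["warm"]]), 1.5)
  expect_lt(abs(d_cold - cfg$trend_profile$high[["cold"]]), 1.5)
})
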