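#' Ground-truth configuration for the synthetic study
#'
#' Defines every knob of the synthetic world the pipeline is exercised on:
#' the spatial grids, the 918-day historical and future windows, the bias
#' injected into the coarse "model" fields, the per-scenario seasonal ozone
#' trends, the observation missingness rate, and the noise structure of the
#' latent truth. Defaults encode the reference study conditions: a +17 ppb
#' mean model overestimate in the historical period, warm/cold seasonal
#' deltas of -4.2/+15.1 ppb under the high-emission scenario and -16.6/-1.7
#' ppb under the moderate scenario, a 10.6% site-day missingness rate, and
#' 3 ensemble members.
#'
#' @param seed Integer master seed; every generator derives its own stream
#'   from it, so a config is fully deterministic.
#' @param n_sites Number of ozone monitoring sites.
#' @param n_cities Number of cities.
#' @param coarse_grid,fine_grid [grid_spec()] objects; fine must nest inside
#'   coarse (default 3 x 3 coarse cells of 2.0 x 2.5 deg over lat 28-34,
#'   lon 110-117.5, fine cells 0.25 x 0.25 deg).
#' @param historical_period,future_period Date vectors `c(start, end)`;
#'   must span equal day counts (defaults: 2013-04-27..2015-10-31 and
#'   2053-04-27..2055-10-31, 918 days each).
#' @param bias_profile Additive model bias in ppb: a single number
#'   (constant across quantiles and months) or `function(q, month)`.
#' @param trend_profile Named list of per-scenario seasonal deltas (ppb),
#'   each `c(warm = ..., cold = ...)`.
#' @param missing_rate Fraction of site-days dropped entirely, in `[0, 1)`.
#' @param hour_missing_rate Fraction of individual hours additionally
#'   dropped, so the within-day 75% completeness rule is exercised too.
#' @param n_ensemble Number of ensemble members.
#' @param truth_mean,seasonal_amp,lat_amp,lon_amp Latent-truth structure
#'   (ppb): overall level, seasonal cycle amplitude peaking mid-July, and
#'   smooth meridional/zonal spatial gradients.
#' @param ar1_phi,weather_sd AR(1) day-to-day weather noise of the truth.
#' @param member_noise_sd Ensemble-member noise sd (ppb).
#' @param site_noise_sd Site-level daily observation noise sd (ppb).
#' @return An object of class `oz_truth_config`.
#' @export
truth_config <- function(seed = 1L,
                         n_sites = 40L,
                         n_cities = 10L,
                         coarse_grid = grid_spec(28, 110, 2.0, 2.5, 3, 3),
                         fine_grid = grid_spec(28, 110, 0.25, 0.25, 24, 30),
                         historical_period = as.Date(c("2013-04-27", "2015-10-31")),
                         future_period = as.Date(c("2053-04-27", "2055-10-31")),
                         bias_profile = 17,
                         trend_profile = list(
                           high = c(warm = -4.2, cold = 15.1),
                           moderate = c(warm = -16.6, cold = -1.7)
                         ),
                         missing_rate = 0.106,
                         hour_missing_rate = 0.02,
                         n_ensemble = 3L,
                         truth_mean = 42,
                         seasonal_amp = 10,
                         lat_amp = 4,
                         lon_amp = 5,
                         ar1_phi = 0.7,
                         weather_sd = 6,
                         member_noise_sd = 2,
                         site_noise_sd = 1.5) {
  assert_nested(fine_grid, coarse_grid)
  historical_period <- as.Date(historical_period)
  future_period <- as.Date(future_period)
  nh <- count_days_in_period(historical_period[1], historical_period[2])
  nf <- count_days_in_period(future_period[1], future_period[2])
  if (nh != nf) abort("historical and future periods must span equal day counts")
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must be in [0, 1)")
  if (!is.function(bias_profile) && !is.numeric(bias_profile)) {
    abort("bias_profile must be a number or function(q, month)")
  }
  for (tp in trend_profile) {
    if (!all(c("warm", "cold") %in% names(tp))) {
      abort("each trend_profile entry needs named warm and cold deltas")
    }
  }
  structure(
    list(seed = as.integer(seed), n_sites = as.integer(n_sites),
         n_cities = as.integer(n_cities),
         coarse_grid = coarse_grid, fine_grid = fine_grid,
         historical_period = historical_period, future_period = future_period,
         n_days = nh,
         bias_profile = bias_profile, trend_profile = trend_profile,
         missing_rate = missing_rate, hour_missing_rate = hour_missing_rate,
         n_ensemble = as.integer(n_ensemble),
         truth_mean = truth_mean, seasonal_amp = seasonal_amp,
         lat_amp = lat_amp, lon_amp = lon_amp,
         ar1_phi = ar1_phi, weather_sd = weather_sd,
         member_noise_sd = member_noise_sd, site_noise_sd = site_noise_sd),
    class = "oz_truth_config"
  )
}

#' @export
print.oz_truth_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<oz_truth_config> seed %d | %d sites, %d cities | %d-day periods\n",
    "  coarse %dx%d (%.2g x %.2g deg), fine %dx%d (%.2g x %.2g deg)\n",
    "  missing_rate %.3f, %d ensemble members\n"),
    x$seed, x$n_sites, x$n_cities, x$n_days,
    x$coarse_grid$nlat, x$coarse_grid$nlon, x$coarse_grid$dlat, x$coarse_grid$dlon,
    x$fine_grid$nlat, x$fine_grid$nlon, x$fine_grid$dlat, x$fine_grid$dlon,
    x$missing_rate, x$n_ensemble))
  invisible(x)
}

period_dates <- function(cfg, period = c("historical", "future")) {
  period <- match.arg(period)
  p <- if (period == "historical") cfg$historical_period else cfg$future_period
  seq(p[1], p[2], by = "day")
}
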