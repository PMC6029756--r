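# Synthetic world: a smooth latent ozone truth plus controlled distortions
# (model bias, future trends, observation noise and missingness). The truth
# is exposed so downscaling error can be measured against ground truth.

#' Latent day-to-day weather anomaly of the synthetic truth
#'
#' A single AR(1) series shared by all locations (one "synoptic" driver),
#' indexed by day position within the period; the future period reuses the
#' historical stream by position, so injected trends are exactly the
#' configured deltas.
#'
#' @param cfg A [truth_config()].
#' @return Numeric vector of length `cfg$n_days`.
#' @keywords internal
truth_weather <- function(cfg) {
  with_seed_local(derive_seed(cfg$seed, "weather"), {
    n <- cfg$n_days
    e <- rnorm(n, sd = cfg$weather_sd * sqrt(1 - cfg$ar1_phi^2))
    w <- numeric(n)
    w[1] <- rnorm(1, sd = cfg$weather_sd)
    for (t in 2:n) w[t] <- cfg$ar1_phi * w[t - 1] + e[t]
    w
  })
}

day_position <- function(cfg, dates, period) {
  start <- if (period == "historical") cfg$historical_period[1] else cfg$future_period[1]
  pos <- as.integer(as.Date(dates) - start) + 1L
  if (any(pos < 1 | pos > cfg$n_days)) abort("date outside the configured period")
  pos
}

#' Pointwise latent truth MDA8 ozone (ppb)
#'
#' Separable smooth structure: overall level + meridional cosine gradient +
#' zonal sine gradient + seasonal cycle peaking mid-July + shared AR(1)
#' weather anomaly. Clamped at 0.
#'
#' @param cfg A [truth_config()].
#' @param lat,lon Coordinates (vectorized with `date`).
#' @param date Dates within the period.
#' @param period `"historical"` or `"future"`.
#' @return Numeric vector (ppb).
#' @export
truth_point <- function(cfg, lat, lon, date, period = "historical") {
  g <- cfg$coarse_grid
  lat_span <- g$nlat * g$dlat
  lon_span <- g$nlon * g$dlon
  latc <- g$lat0 + lat_span / 2
  doy <- lubridate::yday(date)
  w <- truth_weather(cfg)[day_position(cfg, date, period)]
  v <- cfg$truth_mean +
    cfg$lat_amp * cos(pi * (lat - latc) / lat_span) +
    cfg$lon_amp * sin(pi * (lon - g$lon0) / lon_span) +
    cfg$seasonal_amp * cos(2 * pi * (doy - 196) / 365.25) +
    w
  pmax(v, 0)
}

#' Gridded latent truth field
#'
#' The fine-resolution truth is the pointwise truth at fine cell centers;
#' the coarse-resolution truth is its aggregation (mean over nested fine
#' cells), which is exactly what an unbiased coarse model would report.
#'
#' @param cfg A [truth_config()].
#' @param resolution `"fine"` or `"coarse"`.
#' @param period `"historical"` or `"future"`.
#' @param scenario Optional scenario label; when given with
#'   `period = "future"`, the configured seasonal trend is added, i.e. the
#'   returned field is the scenario's true future ozone.
#' @return A grid-field tibble (`cell_id`, `date`, `value`) with the grid
#'   spec in attribute `"grid"`.
#' @export
truth_grid_field <- function(cfg, resolution = c("fine", "coarse"),
                             period = c("historical", "future"),
                             scenario = NULL) {
  resolution <- match.arg(resolution)
  period <- match.arg(period)
  dates <- period_dates(cfg, period)
  cells <- grid_cells(cfg$fine_grid)
  fld <- tidyr::expand_grid(cell_id = cells$cell_id, date = dates) %>%
    left_join(cells[, c("cell_id", "lat", "lon")], by = "cell_id")
  fld$value <- truth_point(cfg, fld$lat, fld$lon, fld$date, period)
  fld <- fld[, c("cell_id", "date", "value")]
  grid <- cfg$fine_grid
  if (resolution == "coarse") {
    map <- fine_to_coarse_map(cfg$fine_grid, cfg$coarse_grid)
    fld <- fld %>%
      left_join(map, by = "cell_id") %>%
      group_by(cell_id = .data$coarse_cell_id, date = .data$date) %>%
      summarise(value = mean(.data$value), .groups = "drop")
    grid <- cfg$coarse_grid
  }
  if (!is.null(scenario)) {
    if (period != "future") abort("scenario trend applies to the future period only")
    fld$value <- pmax(fld$value + scenario_trend(cfg, scenario, fld$date), 0)
  }
  new_grid_field(fld, grid)
}

scenario_trend <- function(cfg, scenario, dates) {
  if (!scenario %in% names(cfg$trend_profile)) {
    abort(sprintf("unknown scenario label '%s' (expected one of: %s)",
                  scenario, paste(names(cfg$trend_profile), collapse = ", ")))
  }
  tp <- cfg$trend_profile[[scenario]]
  unname(tp[season_of(dates)])
}

new_grid_field <- function(df, grid) {
  out <- as_tibble(df)
  attr(out, "grid") <- grid
  class(out) <- c("oz_grid_field", class(out))
  out
}

#' Grid spec of a grid-field tibble
#' @param field A grid-field tibble.
#' @return The [grid_spec()] stored on the field.
#' @export
field_grid <- function(field) {
  g <- attr(field, "grid", exact = TRUE)
  if (is.null(g)) abort("field carries no grid attribute")
  g
}

# Diurnal profile whose maximum 8-hour running mean is exactly 1, so a day
# with level L has MDA8 ~ L before noise.
diurnal_shape <- function() {
  h <- 0:23
  s <- 0.55 + 0.45 * cos(2 * pi * (h - 14.5) / 24)
  m8 <- max(vapply(1:17, function(i) mean(s[i:(i + 7)]), numeric(1)))
  s / m8
}

#' Generate hourly ozone observations at monitoring sites
#'
#' Sites follow a smooth seasonal + diurnal cycle around the latent truth
#' plus site-level noise. Whole site-days are removed at the configured
#' `missing_rate` (emulating monitor outages; the reference network misses
#' 10.6% of site-days) and individual hours are additionally removed at
#' `hour_missing_rate`, so both the within-day 75% completeness rule and
#' full-day gaps are exercised downstream.
#'
#' @param cfg A [truth_config()].
#' @return A tibble `site_id, lat, lon, date, hour, o3_ppb` (missing rows
#'   are absent, not NA), with the site table in attribute `"sites"` and the
#'   dropped site-days in attribute `"dropped_site_days"`.
#' @export
generate_site_hourly_obs <- function(cfg) {
  sites <- generate_sites(cfg)
  dates <- period_dates(cfg, "historical")
  sd_tab <- tidyr::expand_grid(site_id = sites$site_id, date = dates) %>%
    left_join(sites[, c("site_id", "lat", "lon")], by = "site_id")

  lvl <- truth_point(cfg, sd_tab$lat, sd_tab$lon, sd_tab$date, "historical")
  with_seed_local(derive_seed(cfg$seed, "obs"), {
    lvl <- pmax(lvl + rnorm(length(lvl), sd = cfg$site_noise_sd), 0)
    drop_day <- runif(nrow(sd_tab)) < cfg$missing_rate

    shape <- diurnal_shape()
    keep <- sd_tab[!drop_day, ]
    keep$level <- lvl[!drop_day]
    hourly <- tidyr::expand_grid(row = seq_len(nrow(keep)), hour = 0:23)
    hourly <- bind_cols(keep[hourly$row, ], hourly["hour"])
    hourly$o3_ppb <- pmax(
      hourly$level * shape[hourly$hour + 1] + rnorm(nrow(hourly), sd = 1), 0)
    drop_hour <- runif(nrow(hourly)) < cfg$hour_missing_rate
    out <- hourly[!drop_hour,
                  c("site_id", "lat", "lon", "date", "hour", "o3_ppb")]
    attr(out, "sites") <- sites
    attr(out, "dropped_site_days") <-
      as_tibble(sd_tab[drop_day, c("site_id", "date")])
    out
  })
}

#' Monitoring-site table
#'
#' One site is placed inside each city (cities without a site are possible
#' only if `n_sites < n_cities`, in which case uncovered cities are flagged
#' with a warning); remaining sites are scattered uniformly over the domain.
#'
#' @param cfg A [truth_config()].
#' @return Tibble `site_id, lat, lon, city_id` (`NA` city for background
#'   sites).
#' @export
generate_sites <- function(cfg) {
  cities <- city_geometry(cfg)
  g <- cfg$coarse_grid
  lat_hi <- g$lat0 + g$nlat * g$dlat
  lon_hi <- g$lon0 + g$nlon * g$dlon
  with_seed_local(derive_seed(cfg$seed, "sites"), {
    n_in_city <- min(cfg$n_sites, cfg$n_cities)
    in_city <- cities[seq_len(n_in_city), ]
    city_sites <- tibble(
      site_id = sprintf("S%03d", seq_len(n_in_city)),
      lat = runif(n_in_city, in_city$lat_min, in_city$lat_max),
      lon = runif(n_in_city, in_city$lon_min, in_city$lon_max),
      city_id = in_city$city_id
    )
    n_bg <- cfg$n_sites - n_in_city
    bg_sites <- tibble(
      site_id = sprintf("S%03d", n_in_city + seq_len(n_bg)),
      lat = runif(n_bg, g$lat0, lat_hi),
      lon = runif(n_bg, g$lon0, lon_hi),
      city_id = NA_character_
    )
    if (n_in_city < cfg$n_cities) {
      warn(sprintf("%d cities have no monitoring site",
                   cfg$n_cities - n_in_city))
    }
    bind_rows(city_sites, bg_sites)
  })
}

#' Generate coarse chemistry-climate-model daily MDA8 fields
#'
#' The historical field is the coarse-aggregated latent truth plus the
#' configured bias profile plus member-specific noise (members share the
#' truth and differ only in their noise stream, emulating perturbed initial
#' conditions). The future field is additionally shifted by the scenario's
#' seasonal trend. The historical field does not depend on the scenario.
#'
#' @param cfg A [truth_config()].
#' @param scenario Scenario label (a name of `cfg$trend_profile`, by default
#'   `"moderate"` or `"high"`).
#' @param member Ensemble member index in `1..cfg$n_ensemble`.
#' @param period `"historical"` or `"future"`.
#' @return A coarse grid-field tibble (`cell_id`, `date`, `value` in ppb).
#' @export
generate_coarse_model_daily <- function(cfg, scenario, member,
                                        period = c("historical", "future")) {
  period <- match.arg(period)
  if (!scenario %in% names(cfg$trend_profile)) {
    abort(sprintf("unknown scenario label '%s'", scenario))
  }
  if (!(member %in% seq_len(cfg$n_ensemble))) {
    abort(sprintf("member must be in 1..%d", cfg$n_ensemble))
  }
  fld <- truth_grid_field(cfg, "coarse", period)
  grid <- field_grid(fld)

  # injected additive bias, constant or quantile/month dependent
  if (is.function(cfg$bias_profile)) {
    fld <- fld %>%
      group_by(.data$cell_id, month = lubridate::month(.data$date)) %>%
      mutate(q = (rank(.data$value) - 0.5) / n()) %>%
      ungroup() %>%
      mutate(value = .data$value + cfg$bias_profile(.data$q, .data$month)) %>%
      select("cell_id", "date", "value")
  } else {
    fld$value <- fld$value + cfg$bias_profile
  }

  if (period == "future") {
    fld$value <- fld$value + scenario_trend(cfg, scenario, fld$date)
  }

  noise_label <- if (period == "historical") {
    sprintf("model-hist-m%d", member)
  } else {
    sprintf("model-fut-%s-m%d", scenario, member)
  }
  with_seed_local(derive_seed(cfg$seed, noise_label), {
    fld$value <- pmax(fld$value + rnorm(nrow(fld), sd = cfg$member_noise_sd), 0)
  })
  new_grid_field(fld, grid)
}
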