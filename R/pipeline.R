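# End-to-end experiment: synth -> metrics -> downscale -> assess ->
# uncertainty -> decomposition, with a run manifest for reproducibility.

#' Experiment configuration
#'
#' Bundles the ground-truth config with run-level settings. Defaults
#' reproduce the reference design dimensions: 918-day periods, two climate
#' scenarios, six population scenarios, 3 ensemble members, 1,000
#' coefficient draws, the warm/cold seasonal split, and K = 99 quantile
#' points.
#'
#' @param seed Master seed.
#' @param n_draws Monte Carlo coefficient draws.
#' @param K Quantile points for the bias maps.
#' @param scenarios Climate scenario labels to run (names of the truth
#'   config's trend profiles).
#' @param decompose_scenarios Population scenarios to decompose (default:
#'   all with rate changes).
#' @param ... Passed to [truth_config()].
#' @return An `oz_run_config` list.
#' @export
run_config <- function(seed = 1L, n_draws = 1000, K = 99,
                       scenarios = NULL, decompose_scenarios = NULL, ...) {
  truth <- truth_config(seed = seed, ...)
  scenarios <- scenarios %||% names(truth$trend_profile)
  bad <- setdiff(scenarios, names(truth$trend_profile))
  if (length(bad)) {
    abort(sprintf("scenarios: unknown label(s) %s", paste(bad, collapse = ", ")))
  }
  structure(list(truth = truth, n_draws = n_draws, K = K,
                 scenarios = scenarios,
                 decompose_scenarios = decompose_scenarios),
            class = "oz_run_config")
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys: `seed`, `n_draws`, `K`, `scenarios`, and a `truth`
#' mapping whose keys are [truth_config()] arguments (`grids` given as
#' `coarse: [lat0, lon0, dlat, dlon, nlat, nlon]` etc.; periods as
#' `[start, end]` date strings). Schema violations are reported with field
#' paths.
#'
#' @param path YAML file.
#' @return An `oz_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  fail <- function(field, msg) abort(sprintf("config %s: %s", field, msg))
  num1 <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1) fail(field, "must be a single number")
    x
  }
  targs <- list()
  t <- y$truth %||% list()
  for (k in c("n_sites", "n_cities", "missing_rate", "hour_missing_rate",
              "n_ensemble", "bias_profile")) {
    if (!is.null(t[[k]])) targs[[k]] <- num1(t[[k]], paste0("truth.", k))
  }
  for (k in c("historical_period", "future_period")) {
    if (!is.null(t[[k]])) {
      d <- tryCatch(as.Date(t[[k]]), error = function(e) NA)
      if (length(d) != 2 || anyNA(d)) fail(paste0("truth.", k),
                                           "must be two ISO dates")
      targs[[k]] <- d
    }
  }
  for (k in c("coarse_grid", "fine_grid")) {
    if (!is.null(t[[k]])) {
      g <- t[[k]]
      if (!is.numeric(unlist(g)) || length(unlist(g)) != 6) {
        fail(paste0("truth.", k),
             "must be [lat0, lon0, dlat, dlon, nlat, nlon]")
      }
      g <- as.numeric(unlist(g))
      targs[[k]] <- grid_spec(g[1], g[2], g[3], g[4], g[5], g[6])
    }
  }
  if (!is.null(t$trend_profile)) {
    tp <- lapply(t$trend_profile, function(x) {
      if (!all(c("warm", "cold") %in% names(x))) {
        fail("truth.trend_profile", "each scenario needs warm and cold deltas")
      }
      c(warm = as.numeric(x$warm), cold = as.numeric(x$cold))
    })
    targs$trend_profile <- tp
  }
  args <- c(list(seed = as.integer(num1(y$seed %||% 1, "seed")),
                 n_draws = num1(y$n_draws %||% 1000, "n_draws"),
                 K = num1(y$K %||% 99, "K")),
            if (!is.null(y$scenarios)) list(scenarios = as.character(y$scenarios)),
            targs)
  do.call(run_config, args)
}

#' Run the full projection experiment on synthetic data
#'
#' Executes every stage: input generation, MDA8 and gridding, BCSD
#' downscaling per climate scenario and ensemble member, city exposure
#' construction, the stratified health impact assessment across the
#' population-scenario ladder, Monte Carlo empirical confidence intervals,
#' the seasonal summary, and the four-factor driver decomposition. With
#' `out_dir` set, interchange files (CSV/NetCDF) and a run manifest with
#' checksums are written.
#'
#' @param config An [run_config()] object.
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages (default TRUE).
#' @return An `oz_experiment` list: `exposures`, `exposure_summary`,
#'   `assessment`, `burden_table`, `seasonal`, `decomposition`,
#'   `draw_table`, `downscale_diagnostics`, `manifest`, `config`.
#' @export
run_experiment <- function(config = run_config(), out_dir = NULL,
                           quiet = TRUE) {
  stopifnot(inherits(config, "oz_run_config"))
  cfg <- config$truth
  say <- function(...) if (!quiet) message(sprintf(...))

  say("stage 1/6: synthetic inputs")
  hourly <- generate_site_hourly_obs(cfg)
  weights <- generate_city_geometry_weights(cfg)
  pop <- generate_population_scenarios(cfg)
  baseline <- generate_baseline_mortality(cfg)
  crfs <- default_crf_table()

  say("stage 2/6: exposure metrics")
  site_daily <- site_daily_mda8(hourly)
  obs_fine <- grid_site_daily(site_daily, cfg$fine_grid)
  obs_coarse <- grid_site_daily(site_daily, cfg$coarse_grid)
  clim_fine <- monthly_climatology(obs_fine)
  clim_coarse <- monthly_climatology(obs_coarse)
  hist_city <- city_series_from_grid(obs_fine, weights)
  city_cells <- unique(weights$cell_id)

  say("stage 3/6: BCSD downscaling")
  combos <- tidyr::expand_grid(scenario = config$scenarios,
                               member = seq_len(cfg$n_ensemble))
  runs <- purrr::pmap(combos, function(scenario, member) {
    mh <- generate_coarse_model_daily(cfg, scenario, member, "historical")
    mf <- generate_coarse_model_daily(cfg, scenario, member, "future")
    ds <- downscale(mh, mf, obs_coarse, clim_coarse, clim_fine,
                    K = config$K, fine_cells = city_cells)
    say("  %s member %d: bias %+.2f -> %+.2f ppb", scenario, member,
        ds$diagnostics$pre_mean_bias, ds$diagnostics$post_mean_bias)
    list(scenario = scenario, member = member, ds = ds)
  })

  say("stage 4/6: city exposures")
  fut_exp <- purrr::map_dfr(runs, function(r) {
    city_series_from_grid(r$ds$fut_fine, weights) %>%
      mutate(period = "future", scenario = r$scenario, member = r$member)
  })
  exposures <- bind_rows(
    hist_city %>% mutate(period = "historical", scenario = NA_character_,
                         member = NA_integer_),
    fut_exp
  )
  exposure_summary <- exposure_summary_table(exposures)
  diagnostics <- purrr::map_dfr(runs, function(r) {
    tibble(scenario = r$scenario, member = r$member,
           pre_mean_bias = r$ds$diagnostics$pre_mean_bias,
           post_mean_bias = r$ds$diagnostics$post_mean_bias)
  })

  say("stage 5/6: health impact assessment")
  assessment <- run_stratified_assessment(exposures, crfs, baseline, pop)
  draw_table <- mc_excess_draws(exposures, crfs, baseline, pop,
                                n_draws = config$n_draws, seed = cfg$seed)
  burden_table <- summarise_eci(draw_table, point = assessment)
  seasonal <- seasonal_summary(draw_table, assessment)

  say("stage 6/6: driver decomposition")
  dec_scen <- config$decompose_scenarios %||%
    pop$scenario_id[pop$has_rate_change]
  decomposition <- purrr::map_dfr(dec_scen, function(s) {
    decompose_drivers(exposures, crfs, baseline, pop, s)
  })

  res <- structure(
    list(config = config, exposures = exposures,
         exposure_summary = exposure_summary,
         assessment = assessment, burden_table = burden_table,
         seasonal = seasonal, decomposition = decomposition,
         draw_table = draw_table, downscale_diagnostics = diagnostics,
         baseline = baseline, pop_scenarios = pop, weights = weights,
         manifest = NULL),
    class = "oz_experiment"
  )
  if (!is.null(out_dir)) res$manifest <- write_experiment(res, out_dir)
  res
}

# Annual/seasonal city means and exceedance, historical and future.
exposure_summary_table <- function(exposures) {
  grp <- exposures %>%
    group_by(.data$period, .data$scenario, .data$member)
  keys <- dplyr::group_keys(grp)
  splits <- dplyr::group_split(grp)
  purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    d <- splits[[i]]
    bind_rows(
      period_mean(d, "year"), period_mean(d, "warm"), period_mean(d, "cold")
    ) %>%
      group_by(.data$season) %>%
      summarise(mean_ppb = mean(.data$mean_ppb), .groups = "drop") %>%
      mutate(exceed_frac = mean(exceedance_fraction(d)$exceedance),
             period = keys$period[i], scenario = keys$scenario[i],
             member = keys$member[i])
  }) %>%
    group_by(.data$period, .data$scenario, .data$season) %>%
    summarise(mean_ppb = mean(.data$mean_ppb),
              exceed_frac = mean(.data$exceed_frac), .groups = "drop")
}

# Seasonal burden summary: per-season excess plus the net yearly change
# computed from the two season strata, with pooled draw eCIs.
seasonal_summary <- function(draw_table, assessment) {
  seas <- summarise_eci(
    draw_table %>% filter(.data$stratum_type == "season"),
    point = assessment %>% filter(.data$stratum_type == "season")
  )
  net_draws <- draw_table %>%
    filter(.data$stratum_type == "season") %>%
    group_by(.data$rcp, .data$pop_scenario, .data$member, .data$draw) %>%
    summarise(excess = sum(.data$excess),
              annual_hist = sum(.data$annual_hist), .groups = "drop") %>%
    mutate(pct = 100 * .data$excess / .data$annual_hist)
  net_point <- assessment %>%
    filter(.data$stratum_type == "season") %>%
    group_by(.data$rcp, .data$pop_scenario, .data$member) %>%
    summarise(excess = sum(.data$excess),
              annual_hist = sum(.data$annual_hist), .groups = "drop") %>%
    group_by(.data$rcp, .data$pop_scenario) %>%
    summarise(excess = mean(.data$excess),
              annual_hist = mean(.data$annual_hist), .groups = "drop")
  net <- net_draws %>%
    group_by(.data$rcp, .data$pop_scenario) %>%
    summarise(lower = empirical_ci(.data$excess)$lower,
              upper = empirical_ci(.data$excess)$upper,
              pct_lower = empirical_ci(.data$pct)$lower,
              pct_upper = empirical_ci(.data$pct)$upper,
              .groups = "drop") %>%
    left_join(net_point, by = c("rcp", "pop_scenario")) %>%
    mutate(stratum_type = "season", stratum = "net",
           pct_change = 100 * .data$excess / .data$annual_hist)
  bind_rows(seas, net) %>%
    arrange(.data$rcp, .data$pop_scenario, .data$stratum)
}

#' Resolution sensitivity: coarse vs fine city exposures
#'
#' Repeats the cause-specific assessment under the no-population-change
#' scenario using city exposures built directly from the coarse-scale
#' bias-corrected projections (city value = weighted mean of coarse cells)
#' and compares with the fine downscaled exposures: per-city and aggregate
#' absolute and percent differences in excess deaths.
#'
#' @param config An [run_config()] object.
#' @return List with `per_city` and `aggregate` tibbles comparing the two
#'   resolutions.
#' @export
resolution_sensitivity <- function(config = run_config()) {
  cfg <- config$truth
  hourly <- generate_site_hourly_obs(cfg)
  weights <- generate_city_geometry_weights(cfg)
  pop <- generate_population_scenarios(cfg)
  baseline <- generate_baseline_mortality(cfg)
  crfs <- default_crf_table() %>% filter(.data$stratum_type == "cause")
  nochange <- pop %>% filter(.data$scenario_id == "NOCHANGE")

  site_daily <- site_daily_mda8(hourly)
  obs_fine <- grid_site_daily(site_daily, cfg$fine_grid)
  obs_coarse <- grid_site_daily(site_daily, cfg$coarse_grid)
  clim_fine <- monthly_climatology(obs_fine)
  clim_coarse <- monthly_climatology(obs_coarse)
  hist_city <- city_series_from_grid(obs_fine, weights)
  w_coarse <- weights_to_coarse(weights, cfg$fine_grid, cfg$coarse_grid)
  city_cells <- unique(weights$cell_id)

  combos <- tidyr::expand_grid(scenario = config$scenarios,
                               member = seq_len(cfg$n_ensemble))
  res <- purrr::pmap_dfr(combos, function(scenario, member) {
    mh <- generate_coarse_model_daily(cfg, scenario, member, "historical")
    mf <- generate_coarse_model_daily(cfg, scenario, member, "future")
    ds <- downscale(mh, mf, obs_coarse, clim_coarse, clim_fine,
                    K = config$K, fine_cells = city_cells)
    fine_city <- city_series_from_grid(ds$fut_fine, weights)
    coarse_city <- city_series_from_grid(ds$fut_corrected, w_coarse)
    one <- function(series, resolution) {
      assess_annual(series, crfs, baseline) %>%
        inner_join(assess_annual(hist_city, crfs, baseline),
                   by = c("city_id", "stratum_type", "stratum"),
                   suffix = c("_fut", "_hist")) %>%
        mutate(excess = .data$annual_attributable_fut -
                 .data$annual_attributable_hist,
               resolution = resolution, scenario = scenario, member = member)
    }
    bind_rows(one(fine_city, "fine"), one(coarse_city, "coarse"))
  })

  per_city <- res %>%
    group_by(.data$scenario, .data$city_id, .data$stratum,
             .data$resolution) %>%
    summarise(excess = mean(.data$excess), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "resolution", values_from = "excess") %>%
    mutate(diff = .data$coarse - .data$fine,
           pct_diff = 100 * .data$diff / abs(.data$fine))
  aggregate <- res %>%
    group_by(.data$scenario, .data$stratum, .data$resolution) %>%
    summarise(excess = sum(.data$excess) /
                dplyr::n_distinct(.data$member), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "resolution", values_from = "excess") %>%
    mutate(diff = .data$coarse - .data$fine,
           pct_diff = 100 * .data$diff / abs(.data$fine))
  list(per_city = per_city, aggregate = aggregate)
}

# Write interchange files + manifest with checksums.
write_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config$truth
  paths <- character()
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    paths[[name]] <<- p
  }
  wcsv(res$exposures, "city_exposures.csv")
  wcsv(res$exposure_summary, "exposure_summary.csv")
  wcsv(res$assessment, "assessment.csv")
  wcsv(res$burden_table, "burden_changes.csv")
  wcsv(res$seasonal, "seasonal_changes.csv")
  wcsv(res$decomposition, "driver_decomposition.csv")
  wcsv(res$downscale_diagnostics, "downscale_diagnostics.csv")
  wcsv(res$baseline, "baseline_mortality.csv")
  wcsv(res$pop_scenarios, "population_scenarios.csv")
  wcsv(res$weights, "city_weights.csv")

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config_as_list(res$config), cfg_path)
  paths[["config.yaml"]] <- cfg_path

  files <- tibble(
    file = names(paths),
    md5 = unname(tools::md5sum(unlist(paths)))
  )
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("ozonehia")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed,
    conventions = list(ugm3_per_ppb = UGM3_PER_PPB,
                       percentile_rule = "type 7 (linear interpolation)",
                       K = res$config$K,
                       annualization = "sum(ADD)/(covered_days/365.25)"),
    files = purrr::pmap(files, function(file, md5) list(file = file, md5 = md5))
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

config_as_list <- function(config) {
  cfg <- config$truth
  g <- function(x) c(x$lat0, x$lon0, x$dlat, x$dlon, x$nlat, x$nlon)
  list(
    seed = cfg$seed, n_draws = config$n_draws, K = config$K,
    scenarios = config$scenarios,
    truth = list(
      n_sites = cfg$n_sites, n_cities = cfg$n_cities,
      coarse_grid = g(cfg$coarse_grid), fine_grid = g(cfg$fine_grid),
      historical_period = format(cfg$historical_period),
      future_period = format(cfg$future_period),
      missing_rate = cfg$missing_rate,
      hour_missing_rate = cfg$hour_missing_rate,
      n_ensemble = cfg$n_ensemble,
      bias_profile = if (is.numeric(cfg$bias_profile)) cfg$bias_profile else "function",
      trend_profile = lapply(cfg$trend_profile, as.list)
    )
  )
}

#' @export
print.oz_experiment <- function(x, ...) {
  cat(sprintf("<oz_experiment> %d cities, scenarios: %s, %d members, %d draws\n",
              x$config$truth$n_cities,
              paste(x$config$scenarios, collapse = "/"),
              x$config$truth$n_ensemble, x$config$n_draws))
  cat("burden_table (all non-accidental, NOCHANGE):\n")
  print(as.data.frame(
    x$burden_table %>%
      filter(.data$stratum == "non-accidental",
             .data$pop_scenario == "NOCHANGE") %>%
      select("rcp", "excess", "lower", "upper", "pct_change")
  ), row.names = FALSE)
  invisible(x)
}
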