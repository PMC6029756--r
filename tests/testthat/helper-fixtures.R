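# Shared fixtures. The "tiny" world (2x2 coarse cells, 1-year periods, 4
# cities) keeps unit tests fast; expensive objects are memoised per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

tiny_cfg <- function(seed = 42L, ...) {
  truth_config(
    seed = seed, n_sites = 12L, n_cities = 4L,
    coarse_grid = grid_spec(28, 110, 2, 2.5, 2, 2),
    fine_grid = grid_spec(28, 110, 0.25, 0.25, 16, 20),
    historical_period = c("2013-04-27", "2014-04-26"),
    future_period = c("2053-04-27", "2054-04-26"),
    ...
  )
}

tiny_run_config <- function(seed = 42L, n_draws = 40, ...) {
  cfg <- tiny_cfg(seed = seed, ...)
  structure(list(truth = cfg, n_draws = n_draws, K = 19,
                 scenarios = names(cfg$trend_profile),
                 decompose_scenarios = "S1"),
            class = "oz_run_config")
}

tiny_experiment <- function() {
  memo("tiny_experiment", run_experiment(tiny_run_config()))
}

# The study-condition run: 918-day periods, 2 climate scenarios x 6
# population scenarios x 3 members, 10 cities, 50 coefficient draws.
study_experiment <- function() {
  memo("study_experiment",
       run_experiment(run_config(seed = 1L, n_draws = 50)))
}

# A 1-city, flat-exposure world where every quantity has a closed form.
flat_series <- function(value = 50, n_days = 30, city_id = "C01",
                        start = as.Date("2013-06-01")) {
  tibble::tibble(city_id = city_id, date = start + 0:(n_days - 1),
                 value = value)
}

# type-7 quantile computed from first principles, as an independent check
manual_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
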