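# broom-style tidy()/glance() methods for the pipeline's result objects.

#' @export
tidy.oz_bias_maps <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "oz_bias_maps")
  out
}

#' @export
glance.oz_bias_maps <- function(x, ...) {
  tibble(
    n_cells = dplyr::n_distinct(x$cell_id),
    n_months = dplyr::n_distinct(x$month),
    K = attr(x, "K"),
    mean_bias = mean(x$bias),
    mean_abs_bias = mean(abs(x$bias)),
    n_unusable = nrow(attr(x, "unusable") %||% tibble())
  )
}

#' @export
tidy.oz_downscale <- function(x, ...) {
  x$diagnostics$month_rmse
}

#' @export
glance.oz_downscale <- function(x, ...) {
  tibble(
    pre_mean_bias = x$diagnostics$pre_mean_bias,
    post_mean_bias = x$diagnostics$post_mean_bias,
    mean_quantile_rmse = mean(x$diagnostics$month_rmse$quantile_rmse)
  )
}

#' @export
tidy.oz_assessment <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "oz_assessment")
  out
}

#' @export
glance.oz_assessment <- function(x, ...) {
  allc <- x %>% filter(.data$stratum == "non-accidental")
  tibble(
    n_cities = dplyr::n_distinct(x$city_id),
    n_strata = dplyr::n_distinct(paste(x$stratum_type, x$stratum)),
    n_members = dplyr::n_distinct(x$member),
    annual_hist_nonaccidental =
      sum(allc$annual_hist[allc$member == allc$member[1] &
                             allc$rcp == allc$rcp[1] &
                             allc$pop_scenario == allc$pop_scenario[1]])
  )
}

#' @export
tidy.oz_decomposition <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(
      c("climate_effect", "size_effect", "aging_effect", "rate_effect"),
      names_to = "driver", values_to = "deaths_per_year"
    ) %>%
    mutate(driver = sub("_effect$", "", .data$driver)) %>%
    select("rcp", "pop_scenario", "member", "driver", "deaths_per_year",
           "total", "annual_hist")
}

#' @export
glance.oz_decomposition <- function(x, ...) {
  tibble(
    n_runs = nrow(x),
    max_additivity_residual = max(abs(
      x$climate_effect + x$size_effect + x$aging_effect + x$rate_effect -
        x$total
    ))
  )
}

#' @export
tidy.oz_experiment <- function(x, ...) {
  x$burden_table
}

#' @export
glance.oz_experiment <- function(x, ...) {
  nc <- x$burden_table %>%
    filter(.data$stratum == "non-accidental", .data$pop_scenario == "NOCHANGE")
  tibble(
    n_cities = x$config$truth$n_cities,
    n_members = x$config$truth$n_ensemble,
    n_draws = x$config$n_draws,
    scenarios = paste(x$config$scenarios, collapse = "/"),
    annual_hist_nonaccidental = nc$annual_hist[1]
  )
}
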