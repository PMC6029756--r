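# ggplot2 views of the main result types.

#' @export
autoplot.oz_bias_maps <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$q, y = .data$bias,
                               colour = factor(.data$month))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cell_id) +
    ggplot2::labs(x = "probability", y = "model - observation bias (ppb)",
                  colour = "month",
                  title = "Monthly quantile bias maps") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.oz_decomposition <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$pop_scenario,
                               y = .data$deaths_per_year,
                               fill = .data$driver)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::stat_summary(ggplot2::aes(y = .data$total, group = 1),
                          fun = mean, geom = "point", shape = 18, size = 3,
                          colour = "black") +
    ggplot2::facet_wrap(~rcp) +
    ggplot2::labs(x = "population scenario",
                  y = "change in annual attributable deaths",
                  title = "Drivers of burden change",
                  subtitle = "point = total change") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.oz_experiment <- function(object, ...) {
  plot_burden_change(object$burden_table)
}

#' Burden-change summary plot
#'
#' Ensemble-mean change in annual attributable deaths with empirical CIs,
#' by stratum, climate scenario, and population scenario.
#'
#' @param burden_table Output of [summarise_eci()].
#' @param stratum_types Stratum types to show (default `"cause"`).
#' @return A ggplot object.
#' @export
plot_burden_change <- function(burden_table, stratum_types = "cause") {
  df <- burden_table %>% filter(.data$stratum_type %in% stratum_types)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$excess,
                                   colour = .data$rcp)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~pop_scenario) +
    ggplot2::labs(x = NULL, y = "change in annual attributable deaths",
                  title = "Future vs historical ozone-attributable mortality") +
    ggplot2::theme_minimal()
}

#' Seasonal burden-change plot
#'
#' Warm-season, cold-season and net changes with empirical CIs.
#'
#' @param seasonal Seasonal summary tibble from [run_experiment()].
#' @param pop_scenario Population scenario to show (default `"NOCHANGE"`).
#' @return A ggplot object.
#' @export
plot_seasonal_change <- function(seasonal, pop_scenario = "NOCHANGE") {
  df <- seasonal %>% filter(.data$pop_scenario == .env$pop_scenario)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$pct_change,
                                   fill = .data$stratum)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * .data$lower / .data$annual_hist,
                   ymax = 100 * .data$upper / .data$annual_hist),
      width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~rcp) +
    ggplot2::labs(x = NULL, y = "change in attributable deaths (%)",
                  title = "Seasonal ozone-attributable mortality change") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' City exposure distribution plot
#'
#' Distribution of city-mean MDA8 by period and scenario.
#'
#' @param exposures Exposure table from [run_experiment()].
#' @return A ggplot object.
#' @export
plot_city_exposures <- function(exposures) {
  df <- exposures %>%
    mutate(run = if_else(.data$period == "historical", "historical",
                         paste0(.data$scenario, " (future)"))) %>%
    group_by(.data$run, .data$city_id, .data$member) %>%
    summarise(mean_ppb = mean(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$run, y = .data$mean_ppb)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "city mean MDA8 ozone (ppb)",
                  title = "City exposure by period and scenario") +
    ggplot2::theme_minimal()
}
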