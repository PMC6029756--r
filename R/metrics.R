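# Exposure metric construction: MDA8 from hourly data, gridding of site
# observations, grid aggregation, monthly climatologies, city-level series
# and summary statistics.

# Window-mean engine shared by the scalar and table interfaces. `mat` is an
# n x 24 matrix of hourly values (NA = missing), columns = local hours 0-23.
mda8_engine <- function(mat, completeness_threshold = 0.75) {
  if (any(mat < 0, na.rm = TRUE)) abort("negative hourly concentration")
  valid <- !is.na(mat)
  need <- ceiling(24 * completeness_threshold)
  day_ok <- rowSums(valid) >= need
  best <- rep(-Inf, nrow(mat))
  v0 <- mat; v0[!valid] <- 0
  for (s in 1:17) {                      # windows start at hours 0..16
    idx <- s:(s + 7)
    nvalid <- rowSums(valid[, idx, drop = FALSE])
    wmean <- rowSums(v0[, idx, drop = FALSE]) / nvalid
    ok <- nvalid >= 6                    # window rule: >= 6 of 8 hours
    best <- pmax(best, ifelse(ok, wmean, -Inf))
  }
  out <- ifelse(day_ok & is.finite(best), best, NA_real_)
  out
}

#' Maximum daily 8-hour average from one day of hourly values
#'
#' The day's maximum over the 17 running 8-hour window means (windows start
#' at local hours 0-16; no cross-midnight windows). A window counts if at
#' least 6 of its 8 hours are valid; the day counts if at least 75% of the
#' 24 hourly slots (18 hours) are valid, otherwise the result is missing.
#'
#' @param hourly Numeric vector of up to 24 hourly concentrations (ppb) in
#'   hour order 0..23, `NA` for missing; shorter vectors are padded with
#'   `NA` at the end.
#' @param completeness_threshold Day-level completeness fraction
#'   (default 0.75).
#' @return MDA8 in ppb, or `NA` if the day is incomplete.
#' @export
#' @examples
#' mda8_from_hourly(rep(60, 24))   # 60
#' mda8_from_hourly(0:23)          # 19.5 (hours 16-23)
mda8_from_hourly <- function(hourly, completeness_threshold = 0.75) {
  if (length(hourly) > 24) abort("more than 24 hourly values")
  v <- c(as.numeric(hourly), rep(NA_real_, 24 - length(hourly)))
  mda8_engine(matrix(v, nrow = 1), completeness_threshold)[1]
}

#' Daily MDA8 series per site from an hourly observation table
#'
#' @param hourly Tibble `site_id, lat, lon, date, hour, o3_ppb` (as from
#'   [generate_site_hourly_obs()]); absent rows are missing hours.
#' @param completeness_threshold Day-level completeness fraction.
#' @return Tibble `site_id, lat, lon, date, mda8` covering every site-date
#'   with at least one hourly value; incomplete days have `NA` mda8.
#' @export
site_daily_mda8 <- function(hourly, completeness_threshold = 0.75) {
  key <- paste(hourly$site_id, hourly$date)
  groups <- !duplicated(key)
  gidx <- match(key, key[groups])
  mat <- matrix(NA_real_, sum(groups), 24)
  mat[cbind(gidx, hourly$hour + 1L)] <- hourly$o3_ppb
  out <- hourly[groups, c("site_id", "lat", "lon", "date")]
  out$mda8 <- mda8_engine(mat, completeness_threshold)
  as_tibble(out) %>% arrange(.data$site_id, .data$date)
}

#' Grid daily site values onto a regular grid
#'
#' Cell value = unweighted mean of the non-missing site values falling in
#' the cell on that day; cell-days with no reporting site are missing.
#'
#' @param site_daily Tibble `site_id, lat, lon, date, mda8` (or a `value`
#'   column).
#' @param grid Target [grid_spec()]; sites outside its extent are an error.
#' @return Grid-field tibble `cell_id, date, value` (only cell-days with
#'   data are present) with the grid attached.
#' @export
grid_site_daily <- function(site_daily, grid) {
  val <- site_daily[["mda8"]] %||% site_daily[["value"]]
  df <- tibble(
    cell_id = grid_locate(grid, site_daily$lat, site_daily$lon),
    date = site_daily$date, value = val
  )
  fld <- df %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$cell_id, .data$date) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  new_grid_field(fld, grid)
}

#' Aggregate a fine grid field to the coarse grid
#'
#' Coarse value = mean of the non-missing nested fine cells; missing only
#' if every nested fine cell is missing that day.
#'
#' @param field Fine grid-field tibble.
#' @param coarse Coarse [grid_spec()] (fine grid taken from the field).
#' @return Coarse grid-field tibble.
#' @export
aggregate_fine_to_coarse <- function(field, coarse) {
  fine <- field_grid(field)
  map <- fine_to_coarse_map(fine, coarse)
  fld <- field %>%
    left_join(map, by = "cell_id") %>%
    filter(!is.na(.data$value)) %>%
    group_by(cell_id = .data$coarse_cell_id, date = .data$date) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  new_grid_field(fld, coarse)
}

#' Per-cell calendar-month climatology of a daily grid field
#'
#' Means pool all days of each calendar month across the years of the
#' period. Cells with no data in a month are filled from the nearest cell
#' (Euclidean distance between centers) holding a value for that month;
#' fill provenance is recorded in the `filled` column.
#'
#' @param field Daily grid-field tibble.
#' @param grid Optional [grid_spec()] (defaults to the field's).
#' @return Tibble `cell_id, month, value, filled` covering every grid cell
#'   and every month present in the field, grid attached.
#' @export
monthly_climatology <- function(field, grid = field_grid(field)) {
  clim <- field %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$cell_id, month = lubridate::month(.data$date)) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  months <- sort(unique(clim$month))
  cells <- grid_cells(grid)
  full <- tidyr::expand_grid(cell_id = cells$cell_id, month = months) %>%
    left_join(clim, by = c("cell_id", "month")) %>%
    mutate(filled = is.na(.data$value))
  if (any(full$filled)) {
    full <- full %>%
      left_join(cells[, c("cell_id", "lat", "lon")], by = "cell_id") %>%
      group_by(.data$month) %>%
      mutate(value = nn_fill(.data$value, .data$lat, .data$lon)) %>%
      ungroup() %>%
      select("cell_id", "month", "value", "filled")
  }
  out <- new_grid_field(full, grid)
  class(out) <- c("oz_climatology", class(out))
  out
}

# nearest-neighbour fill within one month slice
nn_fill <- function(value, lat, lon) {
  miss <- which(is.na(value)); have <- which(!is.na(value))
  if (length(miss) == 0 || length(have) == 0) return(value)
  for (i in miss) {
    d <- (lat[have] - lat[i])^2 + (lon[have] - lon[i])^2
    value[i] <- value[have[which.min(d)]]
  }
  value
}

#' City-level daily series as a weighted mean of grid cells
#'
#' City value = sum of weight x cell value over the city's member cells,
#' with weights renormalized over the non-missing cells of the day; missing
#' only when every member cell is missing.
#'
#' @param field Daily grid-field tibble (fine or coarse).
#' @param weights Tibble `city_id, cell_id, weight` on the same grid.
#' @return Tibble `city_id, date, value` complete over city x date.
#' @export
city_series_from_grid <- function(field, weights) {
  dates <- sort(unique(field$date))
  joined <- weights %>%
    inner_join(as_tibble(field)[, c("cell_id", "date", "value")],
               by = "cell_id", relationship = "many-to-many") %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$city_id, .data$date) %>%
    summarise(value = sum(.data$weight * .data$value) / sum(.data$weight),
              .groups = "drop")
  tidyr::expand_grid(city_id = sort(unique(weights$city_id)), date = dates) %>%
    left_join(joined, by = c("city_id", "date"))
}

#' City-level daily series as an unweighted mean of member stations
#'
#' Alternative to the gridded route ([city_series_from_grid()]): the city
#' value is the plain mean of the non-missing values of the monitoring
#' sites assigned to the city that day.
#'
#' @param site_daily Tibble `site_id, date, mda8` (or `value`).
#' @param site_city Tibble `site_id, city_id` (sites with `NA` city are
#'   ignored), e.g. from [generate_sites()].
#' @return Tibble `city_id, date, value`.
#' @export
city_series_from_sites <- function(site_daily, site_city) {
  val <- site_daily[["mda8"]] %||% site_daily[["value"]]
  dates <- sort(unique(site_daily$date))
  joined <- tibble(site_id = site_daily$site_id, date = site_daily$date,
                   value = val) %>%
    inner_join(site_city %>% filter(!is.na(.data$city_id)) %>%
                 select("site_id", "city_id"), by = "site_id") %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$city_id, .data$date) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  tidyr::expand_grid(city_id = sort(unique(site_city$city_id[
    !is.na(site_city$city_id)])), date = dates) %>%
    left_join(joined, by = c("city_id", "date"))
}

#' Fraction of days above a threshold
#'
#' Share of non-missing days strictly above the threshold (default: the
#' WHO guideline level, 100 ug/m3 ~ 50 ppb), per city.
#'
#' @param series Tibble `city_id, date, value` (a lone `value` column works
#'   too, treated as one entity).
#' @param threshold ppb (default 50).
#' @return Tibble `city_id, exceedance`.
#' @export
exceedance_fraction <- function(series, threshold = 50) {
  series <- as_tibble(series)
  if (!"city_id" %in% names(series)) series$city_id <- "all"
  series %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$city_id) %>%
    summarise(exceedance = mean(.data$value > threshold), .groups = "drop")
}

#' Period mean of a daily series, whole-year or by season
#'
#' @param series Tibble `city_id, date, value`.
#' @param season `"year"` (all days), `"warm"` or `"cold"`.
#' @param seasons A [season_spec()].
#' @return Tibble `city_id, season, mean_ppb` (non-missing days only).
#' @export
period_mean <- function(series, season = "year", seasons = season_spec()) {
  season <- match.arg(season, c("year", "warm", "cold"))
  series <- as_tibble(series)
  if (!"city_id" %in% names(series)) series$city_id <- "all"
  if (season != "year") {
    series <- series %>% filter(season_of(.data$date, seasons) == season)
  }
  series %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$city_id) %>%
    summarise(season = season, mean_ppb = mean(.data$value), .groups = "drop")
}
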