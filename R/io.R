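# Readers/writers for the pipeline's interchange formats: daily grid fields
# as CF-style NetCDF (dimensions time/lat/lon, variable mda8_o3 in ppb),
# tables as CSV.

#' Write a daily grid field to NetCDF
#'
#' @param field Grid-field tibble (`cell_id, date, value`).
#' @param path Output file.
#' @param varname Variable name (default `"mda8_o3"`).
#' @return `path`, invisibly.
#' @export
write_grid_field_nc <- function(field, path, varname = "mda8_o3") {
  grid <- field_grid(field)
  cells <- grid_cells(grid)
  dates <- sort(unique(field$date))
  lats <- sort(unique(cells$lat))
  lons <- sort(unique(cells$lon))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", lons)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", lats)
  dim_time <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                               as.numeric(dates), unlim = TRUE)
  var <- ncdf4::ncvar_def(varname, "ppb", list(dim_lon, dim_lat, dim_time),
                          missval = -9999, prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  arr <- array(NA_real_, c(length(lons), length(lats), length(dates)))
  m <- match(field$cell_id, cells$cell_id)
  arr[cbind(match(cells$lon[m], lons), match(cells$lat[m], lats),
            as.integer(field$date - dates[1]) + 1L)] <- field$value
  arr[is.na(arr)] <- -9999
  ncdf4::ncvar_put(nc, var, arr)
  ncdf4::ncatt_put(nc, 0, "grid_dlat", grid$dlat)
  ncdf4::ncatt_put(nc, 0, "grid_dlon", grid$dlon)
  invisible(path)
}

#' Read a daily grid field from NetCDF
#'
#' @param path NetCDF file written by [write_grid_field_nc()].
#' @param varname Variable name (default `"mda8_o3"`).
#' @return Grid-field tibble.
#' @export
read_grid_field_nc <- function(path, varname = "mda8_o3") {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lons <- ncdf4::ncvar_get(nc, "lon")
  lats <- ncdf4::ncvar_get(nc, "lat")
  times <- as.Date(ncdf4::ncvar_get(nc, "time"), origin = "1970-01-01")
  arr <- ncdf4::ncvar_get(nc, varname, collapse_degen = FALSE)
  arr[arr == -9999] <- NA_real_
  dlat <- ncdf4::ncatt_get(nc, 0, "grid_dlat")$value
  dlon <- ncdf4::ncatt_get(nc, 0, "grid_dlon")$value
  grid <- grid_spec(min(lats) - dlat / 2, min(lons) - dlon / 2,
                    dlat, dlon, length(lats), length(lons))
  cells <- grid_cells(grid)
  df <- tidyr::expand_grid(date = times, lat = lats, lon = lons)
  df <- df[order(df$date, df$lat, df$lon), ]
  df$value <- as.vector(arr[cbind(match(df$lon, lons), match(df$lat, lats),
                                  match(df$date, times))])
  df$cell_id <- grid_locate(grid, df$lat, df$lon)
  new_grid_field(as_tibble(df)[, c("cell_id", "date", "value")], grid)
}

#' Write hourly site observations to CSV (ISO-8601 timestamps)
#'
#' @param hourly Tibble from [generate_site_hourly_obs()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hourly_obs_csv <- function(hourly, path) {
  df <- data.frame(
    site_id = hourly$site_id, lat = hourly$lat, lon = hourly$lon,
    timestamp = sprintf("%sT%02d:00:00Z", format(hourly$date), hourly$hour),
    o3_ppb = hourly$o3_ppb
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read hourly site observations from CSV
#'
#' @param path File written by [write_hourly_obs_csv()].
#' @return Tibble `site_id, lat, lon, date, hour, o3_ppb`.
#' @export
read_hourly_obs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  tibble(site_id = df$site_id, lat = df$lat, lon = df$lon,
         date = as.Date(ts), hour = as.integer(format(ts, "%H")),
         o3_ppb = df$o3_ppb)
}

#' Serialize quantile bias maps to CSV
#'
#' Columns: `cell_id, month, q, q_model, q_obs, bias`.
#'
#' @param maps An `oz_bias_maps` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bias_maps_csv <- function(maps, path) {
  utils::write.csv(as.data.frame(maps), path, row.names = FALSE)
  invisible(path)
}
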