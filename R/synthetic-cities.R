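# Synthetic city geometries and their grid-membership weights.

# Deterministic city rectangles (lat-lon aligned boxes) inside the domain.
city_geometry <- function(cfg) {
  g <- cfg$coarse_grid
  lat_hi <- g$lat0 + g$nlat * g$dlat
  lon_hi <- g$lon0 + g$nlon * g$dlon
  with_seed_local(derive_seed(cfg$seed, "cities"), {
    n <- cfg$n_cities
    h <- runif(n, 0.3, 0.7)    # city extent in lat (deg)
    w <- runif(n, 0.4, 0.8)    # city extent in lon (deg)
    clat <- runif(n, g$lat0 + h / 2, lat_hi - h / 2)
    clon <- runif(n, g$lon0 + w / 2, lon_hi - w / 2)
    tibble(
      city_id = sprintf("C%02d", seq_len(n)),
      lat = clat, lon = clon,
      lat_min = clat - h / 2, lat_max = clat + h / 2,
      lon_min = clon - w / 2, lon_max = clon + w / 2
    )
  })
}

#' City-to-fine-cell membership weights
#'
#' Cities are axis-aligned boxes; each fine grid cell overlapping the box
#' gets a weight equal to its area fraction of the box (plain lat-lon area),
#' so per-city weights sum to 1. These weights drive the "weighted mean of
#' grid cells falling within the city boundary" exposure aggregation.
#'
#' @param cfg A [truth_config()].
#' @return Tibble `city_id, cell_id, weight` (fine cells), with the city
#'   table in attribute `"cities"`.
#' @export
generate_city_geometry_weights <- function(cfg) {
  cities <- city_geometry(cfg)
  out <- purrr::pmap_dfr(cities, function(city_id, lat_min, lat_max,
                                          lon_min, lon_max, ...) {
    w <- rect_cell_weights(cfg$fine_grid, lat_min, lat_max, lon_min, lon_max)
    w$city_id <- city_id
    w
  })
  out <- out[, c("city_id", "cell_id", "weight")]
  attr(out, "cities") <- cities
  out
}

# Area-fraction weights of a rectangle over a grid; weights sum to 1 for a
# rectangle fully inside the grid extent.
rect_cell_weights <- function(grid, lat_min, lat_max, lon_min, lon_max) {
  i0 <- max(1L, floor((lat_min - grid$lat0) / grid$dlat) + 1L)
  i1 <- min(grid$nlat, ceiling((lat_max - grid$lat0) / grid$dlat))
  j0 <- max(1L, floor((lon_min - grid$lon0) / grid$dlon) + 1L)
  j1 <- min(grid$nlon, ceiling((lon_max - grid$lon0) / grid$dlon))
  if (i1 < i0 || j1 < j0) abort("rectangle does not intersect the grid")
  idx <- expand.grid(i = i0:i1, j = j0:j1)
  cell_lat_lo <- grid$lat0 + (idx$i - 1) * grid$dlat
  cell_lon_lo <- grid$lon0 + (idx$j - 1) * grid$dlon
  ov_lat <- pmax(0, pmin(lat_max, cell_lat_lo + grid$dlat) - pmax(lat_min, cell_lat_lo))
  ov_lon <- pmax(0, pmin(lon_max, cell_lon_lo + grid$dlon) - pmax(lon_min, cell_lon_lo))
  area <- ov_lat * ov_lon
  keep <- area > 0
  w <- tibble(
    cell_id = sprintf("r%02dc%02d", idx$i[keep], idx$j[keep]),
    weight = area[keep] / sum(area[keep])
  )
  w
}

#' Lift fine-cell city weights to the coarse grid
#'
#' Used by the resolution sensitivity analysis: the coarse-resolution city
#' exposure is the weighted mean over coarse cells, with weights summed
#' from the member fine cells.
#'
#' @param weights Output of [generate_city_geometry_weights()].
#' @param fine,coarse The two [grid_spec()] objects.
#' @return Tibble `city_id, cell_id, weight` on the coarse grid.
#' @export
weights_to_coarse <- function(weights, fine, coarse) {
  map <- fine_to_coarse_map(fine, coarse)
  weights %>%
    left_join(map, by = "cell_id") %>%
    group_by(.data$city_id, cell_id = .data$coarse_cell_id) %>%
    summarise(weight = sum(.data$weight), .groups = "drop")
}
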