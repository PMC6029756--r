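#' Regular latitude-longitude grid specification
#'
#' A grid is defined by its south-west corner (edge, not center), cell sizes
#' in degrees, and number of cells in each direction. Cell centers are at
#' `lat0 + (i - 0.5) * dlat`, `lon0 + (j - 0.5) * dlon`. The coarse
#' chemistry-climate-model resolution is 2.0 deg lat x 2.5 deg lon; the fine
#' downscaling target is 0.25 deg x 0.25 deg.
#'
#' @param lat0,lon0 South and west edges of the grid (degrees).
#' @param dlat,dlon Cell size (degrees).
#' @param nlat,nlon Number of cells.
#' @return An object of class `oz_grid` (a list).
#' @export
#' @examples
#' grid_spec(28, 110, dlat = 2, dlon = 2.5, nlat = 3, nlon = 3)
grid_spec <- function(lat0, lon0, dlat, dlon, nlat, nlon) {
  stopifnot(dlat > 0, dlon > 0, nlat >= 1, nlon >= 1)
  structure(
    list(lat0 = lat0, lon0 = lon0, dlat = dlat, dlon = dlon,
         nlat = as.integer(nlat), nlon = as.integer(nlon)),
    class = "oz_grid"
  )
}

#' @export
print.oz_grid <- function(x, ...) {
  cat(sprintf("<oz_grid> %d x %d cells, %.3g x %.3g deg, origin (%.3g, %.3g)\n",
              x$nlat, x$nlon, x$dlat, x$dlon, x$lat0, x$lon0))
  invisible(x)
}

#' Cell centers of a grid
#'
#' @param grid An [grid_spec()] object.
#' @return A tibble with `cell_id`, `lat_idx`, `lon_idx`, `lat`, `lon`
#'   (cell-center coordinates), ordered row-major (lat outer, lon inner).
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "oz_grid"))
  idx <- expand.grid(lon_idx = seq_len(grid$nlon), lat_idx = seq_len(grid$nlat))
  tibble(
    cell_id = sprintf("r%02dc%02d", idx$lat_idx, idx$lon_idx),
    lat_idx = idx$lat_idx,
    lon_idx = idx$lon_idx,
    lat = grid$lat0 + (idx$lat_idx - 0.5) * grid$dlat,
    lon = grid$lon0 + (idx$lon_idx - 0.5) * grid$dlon
  ) %>% arrange(.data$lat_idx, .data$lon_idx)
}

#' Locate points on a grid
#'
#' @param grid An [grid_spec()] object.
#' @param lat,lon Point coordinates (degrees), vectorized.
#' @param strict Error if any point falls outside the grid extent
#'   (default TRUE); otherwise outside points get `NA` cell ids.
#' @return Character vector of cell ids.
#' @export
grid_locate <- function(grid, lat, lon, strict = TRUE) {
  i <- floor((lat - grid$lat0) / grid$dlat) + 1
  j <- floor((lon - grid$lon0) / grid$dlon) + 1
  # points exactly on the north/east edge belong to the last cell
  i[lat == grid$lat0 + grid$nlat * grid$dlat] <- grid$nlat
  j[lon == grid$lon0 + grid$nlon * grid$dlon] <- grid$nlon
  out <- i < 1 | i > grid$nlat | j < 1 | j > grid$nlon | is.na(i) | is.na(j)
  if (strict && any(out, na.rm = TRUE)) {
    abort(sprintf("%d point(s) fall outside the grid extent", sum(out)))
  }
  id <- sprintf("r%02dc%02d", i, j)
  id[out] <- NA_character_
  id
}

#' Check that a fine grid nests inside a coarse grid
#'
#' Each coarse cell must contain an integer number of fine cells and the
#' origins must coincide.
#'
#' @param fine,coarse [grid_spec()] objects.
#' @return TRUE (invisibly) or an error.
#' @export
assert_nested <- function(fine, coarse) {
  rlat <- coarse$dlat / fine$dlat
  rlon <- coarse$dlon / fine$dlon
  ok <- abs(rlat - round(rlat)) < 1e-9 && abs(rlon - round(rlon)) < 1e-9 &&
    abs(fine$lat0 - coarse$lat0) < 1e-9 && abs(fine$lon0 - coarse$lon0) < 1e-9 &&
    abs(fine$nlat * fine$dlat - coarse$nlat * coarse$dlat) < 1e-9 &&
    abs(fine$nlon * fine$dlon - coarse$nlon * coarse$dlon) < 1e-9
  if (!ok) abort("fine grid does not nest inside the coarse grid")
  invisible(TRUE)
}

#' Map fine cells to their enclosing coarse cells
#'
#' @param fine,coarse [grid_spec()] objects (fine must nest in coarse).
#' @return Tibble with `cell_id` (fine) and `coarse_cell_id`.
#' @export
fine_to_coarse_map <- function(fine, coarse) {
  assert_nested(fine, coarse)
  cells <- grid_cells(fine)
  cells$coarse_cell_id <- grid_locate(coarse, cells$lat, cells$lon)
  cells[, c("cell_id", "coarse_cell_id")]
}

#' Bilinear interpolation from coarse cell centers to arbitrary points
#'
#' Values are defined at the centers of a regular grid; query points beyond
#' the outermost centers are extrapolated as constants (coordinates clamped
#' to the center bounding box), the standard edge rule for anomaly
#' disaggregation.
#'
#' @param grid An [grid_spec()] object on whose cell centers `values` live.
#' @param values Tibble with `cell_id`, `value` (one time slice). `NA`
#'   allowed; an `NA` corner propagates to points that weight it.
#' @param lat,lon Query points (vectorized).
#' @return Numeric vector of interpolated values.
#' @export
bilinear_interp <- function(grid, values, lat, lon) {
  cells <- grid_cells(grid)
  m <- match(cells$cell_id, values$cell_id)
  v <- values$value[m]
  W <- bilinear_weight_matrix(grid, lat, lon)
  interp_with_na(W, v)
}

# Dense interpolation weight matrix: rows = query points, columns = grid
# cells in grid_cells() order; each row holds the (up to 4) bilinear corner
# weights, with coordinates clamped to the cell-center bounding box so edge
# points get constant extrapolation.
bilinear_weight_matrix <- function(grid, lat, lon) {
  stopifnot(length(lat) == length(lon))
  np <- length(lat)
  clat <- grid$lat0 + (seq_len(grid$nlat) - 0.5) * grid$dlat
  clon <- grid$lon0 + (seq_len(grid$nlon) - 0.5) * grid$dlon
  qla <- pmin(pmax(lat, clat[1]), clat[grid$nlat])
  qlo <- pmin(pmax(lon, clon[1]), clon[grid$nlon])

  i0 <- pmin(pmax(findInterval(qla, clat), 1L), max(grid$nlat - 1L, 1L))
  j0 <- pmin(pmax(findInterval(qlo, clon), 1L), max(grid$nlon - 1L, 1L))
  i1 <- pmin(i0 + 1L, grid$nlat)
  j1 <- pmin(j0 + 1L, grid$nlon)
  ty <- if (grid$nlat > 1) (qla - clat[i0]) / grid$dlat else rep(0, np)
  tx <- if (grid$nlon > 1) (qlo - clon[j0]) / grid$dlon else rep(0, np)

  # grid_cells order is row-major with lat outer: col = (i-1)*nlon + j
  col <- function(i, j) (i - 1L) * grid$nlon + j
  W <- matrix(0, np, grid$nlat * grid$nlon)
  rows <- seq_len(np)
  add <- function(i, j, w) {
    idx <- cbind(rows, col(i, j))
    W[idx] <<- W[idx] + w
  }
  add(i0, j0, (1 - ty) * (1 - tx))
  add(i0, j1, (1 - ty) * tx)
  add(i1, j0, ty * (1 - tx))
  add(i1, j1, ty * tx)
  W
}

# W %*% v with NA poisoning only through strictly positive weights
interp_with_na <- function(W, v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 1)
  v0 <- v; v0[is.na(v)] <- 0
  out <- W %*% v0
  touched <- (W > 0) %*% matrix(as.numeric(is.na(v)), nrow = nrow(v))
  out[touched > 0] <- NA_real_
  if (ncol(out) == 1) out <- drop(out)
  out
}
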