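#' Grid specification for all raster layers
#'
#' A `grid_spec` is the georeference contract shared by every raster in an
#' analysis: a regular lon/lat grid in decimal degrees (WGS84) with a fixed
#' cell size and a nodata sentinel. Cell `(i, j)` (row `i` counted from the
#' southern edge, column `j` from the western edge) covers the half-open box
#' `[lon_min + (j-1)*cell_size, lon_min + j*cell_size) x
#'  [lat_min + (i-1)*cell_size, lat_min + i*cell_size)`.
#'
#' @param lon_min,lat_min,lon_max,lat_max extent bounds in decimal degrees.
#' @param cell_size cell edge length in degrees (e.g. `0.25` or `2.5/60`).
#' @param nodata_value sentinel written to file for missing cells.
#' @return an object of class `grid_spec` with fields `lon_min`, `lat_min`,
#'   `lon_max`, `lat_max`, `cell_size`, `n_rows`, `n_cols`, `nodata_value`.
#' @examples
#' g <- make_grid(-10, 33, 45, 72, 0.25)
#' g$n_cols  # 220
#' g$n_rows  # 156
#' @export
make_grid <- function(lon_min, lat_min, lon_max, lat_max, cell_size,
                      nodata_value = -9999) {
  stopifnot(is.numeric(lon_min), is.numeric(lat_min),
            is.numeric(lon_max), is.numeric(lat_max),
            is.numeric(cell_size), cell_size > 0)
  if (!(lon_min < lon_max) || !(lat_min < lat_max)) {
    stop("extent bounds must be ordered: lon_min < lon_max, lat_min < lat_max",
         call. = FALSE)
  }
  n_cols <- (lon_max - lon_min) / cell_size
  n_rows <- (lat_max - lat_min) / cell_size
  if (abs(n_cols - round(n_cols)) > 1e-9 || abs(n_rows - round(n_rows)) > 1e-9) {
    stop("cell_size does not divide the extent spans (tolerance 1e-9)",
         call. = FALSE)
  }
  structure(list(
    lon_min = lon_min, lat_min = lat_min,
    lon_max = lon_max, lat_max = lat_max,
    cell_size = cell_size,
    n_rows = as.integer(round(n_rows)),
    n_cols = as.integer(round(n_cols)),
    nodata_value = nodata_value
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d rows x %d cols @ %g deg\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  lon [%g, %g)  lat [%g, %g)  nodata %g\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max, x$nodata_value))
  invisible(x)
}

grid_equal <- function(a, b, tol = 1e-9) {
  all(abs(c(a$lon_min - b$lon_min, a$lat_min - b$lat_min,
            a$cell_size - b$cell_size)) < tol) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Map points to grid cells
#'
#' Returns the (row, col) indices of the cells containing the given points
#' under the half-open cell convention; points outside the extent get `NA`.
#'
#' @param grid a [make_grid()] object.
#' @param lon,lat point coordinates in decimal degrees.
#' @return a list with integer vectors `row` and `col`.
#' @export
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$lon_min) / grid$cell_size) + 1
  row <- floor((lat - grid$lat_min) / grid$cell_size) + 1
  bad <- lon < grid$lon_min | lon >= grid$lon_max |
         lat < grid$lat_min | lat >= grid$lat_max
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Cell-center coordinates
#'
#' @param grid a [make_grid()] object.
#' @param row,col integer cell indices (row 1 = southern edge).
#' @return a list with numeric vectors `lon` and `lat`.
#' @export
cell_center <- function(grid, row, col) {
  list(lon = grid$lon_min + (col - 0.5) * grid$cell_size,
       lat = grid$lat_min + (row - 0.5) * grid$cell_size)
}

#' Latitude of each grid row's cell centers
#' @param grid a [make_grid()] object.
#' @return numeric vector of length `n_rows`.
#' @export
row_latitudes <- function(grid) {
  grid$lat_min + (seq_len(grid$n_rows) - 0.5) * grid$cell_size
}

# Matrix of cell-center latitudes (n_rows x n_cols), used for latitude
# weighting and latitude-graded scenario shifts.
latitude_matrix <- function(grid) {
  matrix(row_latitudes(grid), nrow = grid$n_rows, ncol = grid$n_cols)
}
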