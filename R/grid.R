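#' Regular longitude-latitude analysis grid
#'
#' Builds the uniform lon/lat grid on which all fields, suitability maps and
#' area calculations live. Cell centres are offset half a cell from the range
#' edges, so the range limits are cell boundaries.
#'
#' @param lon_range numeric length-2, degrees east, within [-180, 180].
#' @param lat_range numeric length-2, degrees north, within [-90, 90].
#' @param cell_size cell edge length in degrees (default 0.25).
#' @return an object of class `ps_grid` with cell-centre vectors `lon`, `lat`.
#' @export
make_grid <- function(lon_range, lat_range, cell_size = 0.25) {
  stopifnot(length(lon_range) == 2, length(lat_range) == 2, cell_size > 0)
  if (lat_range[1] < -90 || lat_range[2] > 90)
    stop("lat_range must lie within [-90, 90]")
  if (diff(lon_range) < 2 * cell_size || diff(lat_range) < 2 * cell_size)
    stop("degenerate grid: need at least 2 cells per axis")
  lon <- seq(lon_range[1] + cell_size / 2, lon_range[2] - cell_size / 2,
             by = cell_size)
  lat <- seq(lat_range[1] + cell_size / 2, lat_range[2] - cell_size / 2,
             by = cell_size)
  structure(list(lon = lon, lat = lat, cell_size = cell_size,
                 lon_range = lon_range, lat_range = lat_range),
            class = "ps_grid")
}

#' @export
print.ps_grid <- function(x, ...) {
  cat(sprintf("<ps_grid> %d x %d cells of %g deg, lon [%g, %g], lat [%g, %g]\n",
              length(x$lon), length(x$lat), x$cell_size,
              x$lon_range[1], x$lon_range[2], x$lat_range[1], x$lat_range[2]))
  invisible(x)
}

#' Map coordinates to grid cell indices
#'
#' @param grid a `ps_grid`.
#' @param lon,lat coordinate vectors (recycled to common length).
#' @return data.frame with integer columns `i` (lon index) and `j` (lat index);
#'   NA outside the grid.
#' @export
cell_index <- function(grid, lon, lat) {
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  i <- floor((lon - grid$lon_range[1]) / grid$cell_size) + 1L
  j <- floor((lat - grid$lat_range[1]) / grid$cell_size) + 1L
  i[lon == grid$lon_range[2]] <- length(grid$lon)  # top edge belongs to last cell
  j[lat == grid$lat_range[2]] <- length(grid$lat)
  i[i < 1L | i > length(grid$lon)] <- NA_integer_
  j[j < 1L | j > length(grid$lat)] <- NA_integer_
  data.frame(i = as.integer(i), j = as.integer(j))
}

#' Spherical cell areas of a regular grid
#'
#' Area of each cell on the sphere, `R^2 * dlambda * (sin(phi_top) -
#' sin(phi_bottom))` with R = 6371 km. Returned as a matrix aligned with
#' `[lon, lat]` field matrices (rows = lon, columns = lat).
#'
#' @param grid a `ps_grid`.
#' @param radius_km sphere radius, km.
#' @return matrix of areas in km^2, dimension `length(grid$lon)` x
#'   `length(grid$lat)`.
#' @export
cell_areas <- function(grid, radius_km = 6371) {
  dl <- grid$cell_size * pi / 180
  top <- (grid$lat + grid$cell_size / 2) * pi / 180
  bot <- (grid$lat - grid$cell_size / 2) * pi / 180
  band <- radius_km^2 * dl * (sin(top) - sin(bot))   # per-latitude band area
  matrix(rep(band, each = length(grid$lon)),
         nrow = length(grid$lon), ncol = length(grid$lat))
}

#' Bilinear regridding of a field matrix onto a new grid
#'
#' Interpolates a `[lon, lat]` matrix from one regular grid to another.
#' Target cells outside the convex span of source cell centres take the
#' nearest-edge value (constant extrapolation); missing source cells propagate.
#'
#' @param values matrix on `from` (rows = lon, cols = lat).
#' @param from,to `ps_grid` objects.
#' @return matrix on `to`.
#' @export
regrid_bilinear <- function(values, from, to) {
  stopifnot(identical(dim(values), c(length(from$lon), length(from$lat))))
  fx <- from$lon; fy <- from$lat
  interp_axis <- function(coord, centres) {
    coord <- pmin(pmax(coord, centres[1]), centres[length(centres)])
    i0 <- findInterval(coord, centres, rightmost.closed = TRUE)
    i0 <- pmin(pmax(i0, 1L), length(centres) - 1L)
    w <- (coord - centres[i0]) / (centres[i0 + 1L] - centres[i0])
    list(i0 = i0, w = pmin(pmax(w, 0), 1))
  }
  ax <- interp_axis(to$lon, fx); ay <- interp_axis(to$lat, fy)
  out <- matrix(NA_real_, length(to$lon), length(to$lat))
  for (j in seq_along(to$lat)) {
    j0 <- ay$i0[j]; wy <- ay$w[j]
    v00 <- values[ax$i0, j0];     v10 <- values[ax$i0 + 1L, j0]
    v01 <- values[ax$i0, j0 + 1L]; v11 <- values[ax$i0 + 1L, j0 + 1L]
    out[, j] <- (1 - ax$w) * (1 - wy) * v00 + ax$w * (1 - wy) * v10 +
      (1 - ax$w) * wy * v01 + ax$w * wy * v11
  }
  out
}

#' Great-circle distance
#'
#' Haversine distance in km between coordinate pairs (vectorized).
#' @param lon1,lat1,lon2,lat2 degrees.
#' @param radius_km sphere radius, km.
#' @return numeric vector of distances, km.
#' @export
gc_dist_km <- function(lon1, lat1, lon2, lat2, radius_km = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

# Derive a reproducible 32-bit sub-seed for a named component from a top seed.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% .Machine$integer.max)
}

# Long-format data.frame view of a [lon, lat] matrix (for CSV round trips).
grid_to_df <- function(grid, values) {
  data.frame(lon = rep(grid$lon, times = length(grid$lat)),
             lat = rep(grid$lat, each = length(grid$lon)),
             value = as.vector(values))
}
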