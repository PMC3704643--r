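#' Grid specification for an ocean-current domain
#'
#' A regular lon/lat/depth grid with a land mask and bathymetry, the spatial
#' scaffold every other object in the package refers to. Axes are cell
#' centers, strictly increasing; depth levels are layer midpoints in meters,
#' positive downward. The representative horizontal cell width
#' \code{cell_length_m} enters only the horizontal diffusivity
#' (\code{\link{horizontal_diffusivity}}) and the time-step admissibility rule
#' (\code{\link{choose_time_step}}); by default it is evaluated at the domain
#' mid-latitude as the mean of the zonal and meridional cell widths.
#'
#' @param lon,lat cell-center axes in degrees east / north, strictly increasing.
#' @param depth layer-midpoint depths in meters, positive down, increasing.
#' @param land_mask logical matrix \code{[nlon, nlat]}, \code{TRUE} on land.
#' @param bathymetry numeric matrix \code{[nlon, nlat]}, seafloor depth (m) on
#'   sea cells; values on land cells are ignored (stored as 0).
#' @param cell_length_m representative horizontal cell width in meters;
#'   computed from the grid at mid-latitude when \code{NULL}.
#' @return an object of class \code{grid_spec}.
#' @export
grid_spec <- function(lon, lat, depth = 0.5, land_mask = NULL,
                      bathymetry = NULL, cell_length_m = NULL) {
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0)) {
    stop_domain("grid axes must be strictly increasing")
  }
  if (length(depth) > 1 && any(diff(depth) <= 0)) {
    stop_domain("depth levels must be strictly increasing (positive down)")
  }
  nlon <- length(lon); nlat <- length(lat)
  if (is.null(land_mask)) {
    land_mask <- matrix(FALSE, nlon, nlat)
  }
  if (!identical(dim(land_mask), c(nlon, nlat))) {
    stop_domain("land_mask must be a [nlon, nlat] matrix")
  }
  if (is.null(bathymetry)) {
    bathymetry <- matrix(max(depth) * 2, nlon, nlat)
  }
  if (!identical(dim(bathymetry), c(nlon, nlat))) {
    stop_domain("bathymetry must be a [nlon, nlat] matrix")
  }
  bathymetry[land_mask] <- 0
  if (any(bathymetry[!land_mask] <= 0)) {
    stop_domain("bathymetry must be > 0 on sea cells")
  }
  if (is.null(cell_length_m)) {
    midlat <- (min(lat) + max(lat)) / 2
    dlon <- mean(diff(lon)) * M_PER_DEG * cos(midlat * pi / 180)
    dlat <- mean(diff(lat)) * M_PER_DEG
    cell_length_m <- (dlon + dlat) / 2
  }
  if (cell_length_m <= 0) stop_domain("cell_length_m must be > 0")
  structure(list(
    lon = lon, lat = lat, depth = depth,
    lon_edges = axis_edges(lon), lat_edges = axis_edges(lat),
    land_mask = land_mask, bathymetry = bathymetry,
    cell_length_m = cell_length_m
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "grid_spec: %d x %d cells, %d depth level(s), cell ~%.0f m, %.1f%% land\n",
    length(x$lon), length(x$lat), length(x$depth), x$cell_length_m,
    100 * mean(x$land_mask)))
  invisible(x)
}

# Cell index of positions; returns i (lon) and j (lat), NA when outside the
# domain's outer edges.
grid_cell <- function(grid, lon, lat) {
  i <- findInterval(lon, grid$lon_edges, rightmost.closed = TRUE)
  j <- findInterval(lat, grid$lat_edges, rightmost.closed = TRUE)
  i[i < 1L | i > length(grid$lon)] <- NA_integer_
  j[j < 1L | j > length(grid$lat)] <- NA_integer_
  list(i = i, j = j)
}

# TRUE where the position falls on a land cell (NA outside domain -> FALSE).
is_land_at <- function(grid, lon, lat) {
  ij <- grid_cell(grid, lon, lat)
  out <- rep(FALSE, length(lon))
  ok <- !is.na(ij$i) & !is.na(ij$j)
  out[ok] <- grid$land_mask[cbind(ij$i[ok], ij$j[ok])]
  out
}

#' Daily 3-D velocity field
#'
#' Daily snapshots of the current velocity on a \code{\link{grid_spec}}.
#' Components are arrays of dimension \code{[nlon, nlat, ndepth, ntime]} in
#' m/s. Land cells must carry exactly zero velocity: the tracker's coastal
#' standstill rule relies on the flow vanishing at the land interface. A
#' missing \code{w} is treated as identically zero (purely horizontal flow).
#'
#' @param times vector of day indices (1-based) or dates, one per snapshot.
#' @param u,v zonal and meridional velocity arrays (m/s).
#' @param w vertical velocity array (m/s, positive down) or \code{NULL}.
#' @param grid the \code{\link{grid_spec}} the arrays live on.
#' @return an object of class \code{velocity_field}.
#' @export
velocity_field <- function(times, u, v, w = NULL, grid) {
  expect_dim <- c(length(grid$lon), length(grid$lat), length(grid$depth),
                  length(times))
  for (nm in c("u", "v")) {
    a <- get(nm)
    if (!identical(dim(a), as.integer(expect_dim))) {
      stop_domain(sprintf("%s must have dim [nlon, nlat, ndepth, ntime] = [%s]",
                          nm, paste(expect_dim, collapse = ", ")))
    }
    if (any(!is.finite(a))) stop_domain(nm, " contains non-finite values")
  }
  if (!is.null(w) && !identical(dim(w), as.integer(expect_dim))) {
    stop_domain("w must match u in dimension")
  }
  land <- which(grid$land_mask)
  if (length(land)) {
    nz <- length(grid$lon) * length(grid$lat)
    # check a sample slab for nonzero land velocity (full check in validator)
    for (k in seq_along(grid$depth)) for (t in seq_along(times)) {
      off <- (k - 1L + (t - 1L) * length(grid$depth)) * nz
      if (any(u[land + off] != 0) || any(v[land + off] != 0)) {
        stop_domain("velocity must be exactly zero on land cells")
      }
    }
  }
  structure(list(times = times, u = u, v = v, w = w),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf("velocity_field: %d day(s), %d x %d x %d, max speed %.3f m/s\n",
              d[4], d[1], d[2], d[3], max_speed(x)))
  invisible(x)
}

#' Maximum current speed of a field
#'
#' The maximum of \code{sqrt(u^2 + v^2)} over all cells and days, used to
#' check time-step admissibility against \code{\link{choose_time_step}}.
#'
#' @param field a \code{\link{velocity_field}}.
#' @return scalar speed in m/s.
#' @export
max_speed <- function(field) {
  sqrt(max(field$u^2 + field$v^2))
}

#' An MPA site (release/settlement polygon)
#'
#' @param id integer identifier (graph node id).
#' @param name label.
#' @param ring two-column matrix of (lon, lat) vertices; closed automatically.
#' @param area_km2 surface area; computed on the sphere when \code{NULL}.
#' @param ecoregion optional label.
#' @return an object of class \code{mpa_site}.
#' @export
mpa_site <- function(id, name, ring, area_km2 = NULL, ecoregion = NA_character_) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2) stop_domain("ring must be a 2-column (lon, lat) matrix")
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  if (is.null(area_km2)) {
    # shoelace area on the local tangent plane (R = 6371 km); accurate for
    # the small coastal polygons MPAs are
    v <- ring[-nrow(ring), , drop = FALSE]
    latc <- mean(v[, 2]) * pi / 180
    x <- v[, 1] * M_PER_DEG * cos(latc) / 1000
    y <- v[, 2] * M_PER_DEG / 1000
    nv <- length(x)
    nxt <- c(seq_len(nv)[-1], 1L)
    area_km2 <- abs(sum(x * y[nxt] - x[nxt] * y)) / 2
  }
  if (area_km2 <= 0) stop_domain("area_km2 must be > 0")
  structure(list(id = as.integer(id), name = as.character(name), ring = ring,
                 area_km2 = area_km2, ecoregion = ecoregion),
            class = "mpa_site")
}

#' @export
print.mpa_site <- function(x, ...) {
  cat(sprintf("mpa_site %d '%s': %.1f km2, centroid (%.3f, %.3f)\n",
              x$id, x$name, x$area_km2,
              mean(x$ring[-nrow(x$ring), 1]), mean(x$ring[-nrow(x$ring), 2])))
  invisible(x)
}

# Polygon centroid (vertex mean; polygons here are small and convex-ish).
mpa_centroid <- function(mpa) {
  v <- mpa$ring[-nrow(mpa$ring), , drop = FALSE]
  colMeans(v)
}
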