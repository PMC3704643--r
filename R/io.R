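#' Write a velocity field to NetCDF
#'
#' CF-style file with dimensions (lon, lat, depth, time) and variables
#' \code{u}, \code{v}, \code{w} (m s-1), \code{bathymetry} (m) and integer
#' \code{mask} (1 = land). Double precision throughout so
#' \code{\link{read_velocity_field}} inverts it bit-identically.
#'
#' @param field a \code{\link{velocity_field}}.
#' @param grid the matching \code{\link{grid_spec}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_velocity_field <- function(field, grid, path) {
  if (!identical(dim(field$u)[1:3],
                 c(length(grid$lon), length(grid$lat), length(grid$depth)))) {
    stop_domain("field dimensions do not match grid")
  }
  dl <- ncdf4::ncdim_def("lon", "degrees_east", grid$lon)
  dp <- ncdf4::ncdim_def("lat", "degrees_north", grid$lat)
  dz <- ncdf4::ncdim_def("depth", "m", grid$depth)
  dt <- ncdf4::ncdim_def("time", "days", as.numeric(field$times),
                         unlim = TRUE)
  mkvar <- function(nm) ncdf4::ncvar_def(nm, "m s-1", list(dl, dp, dz, dt),
                                         prec = "double")
  vu <- mkvar("u"); vv <- mkvar("v"); vw <- mkvar("w")
  vb <- ncdf4::ncvar_def("bathymetry", "m", list(dl, dp), prec = "double")
  vm <- ncdf4::ncvar_def("mask", "1", list(dl, dp), prec = "integer")
  vc <- ncdf4::ncvar_def("cell_length", "m", list(), prec = "double")
  nc <- ncdf4::nc_create(path, list(vu, vv, vw, vb, vm, vc))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vu, field$u)
  ncdf4::ncvar_put(nc, vv, field$v)
  w <- if (is.null(field$w)) array(0, dim(field$u)) else field$w
  ncdf4::ncvar_put(nc, vw, w)
  ncdf4::ncvar_put(nc, vb, grid$bathymetry)
  ncdf4::ncvar_put(nc, vm, grid$land_mask * 1L)
  ncdf4::ncvar_put(nc, vc, grid$cell_length_m)
  invisible(path)
}

#' Read a velocity field from NetCDF
#'
#' Expects dimensions (lon, lat, depth, time) and variables \code{u},
#' \code{v}; \code{w} is assumed zero when absent, land is taken from a
#' \code{mask} variable (or inferred all-sea). Land cells are zero-filled.
#'
#' @param path NetCDF file.
#' @return list with elements \code{field} and \code{grid}.
#' @export
read_velocity_field <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  for (d in c("lon", "lat", "depth", "time")) {
    if (!d %in% names(nc$dim)) stop_domain("dimension '", d, "' missing")
  }
  for (v in c("u", "v")) {
    if (!v %in% names(nc$var)) stop_domain("variable '", v, "' missing")
    un <- ncdf4::ncatt_get(nc, v, "units")
    if (un$hasatt && !grepl("m ?s-?1|m/s", un$value)) {
      stop_domain("variable '", v, "' has units '", un$value,
                  "', expected m s-1")
    }
  }
  lon <- as.numeric(nc$dim$lon$vals); lat <- as.numeric(nc$dim$lat$vals)
  depth <- as.numeric(nc$dim$depth$vals)
  times <- as.numeric(nc$dim$time$vals)
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0)) {
    stop_domain("lon/lat axes must be strictly increasing")
  }
  nlon <- length(lon); nlat <- length(lat)
  mask <- if ("mask" %in% names(nc$var)) {
    matrix(ncdf4::ncvar_get(nc, "mask"), nlon, nlat) > 0
  } else matrix(FALSE, nlon, nlat)
  bathy <- if ("bathymetry" %in% names(nc$var)) {
    matrix(ncdf4::ncvar_get(nc, "bathymetry"), nlon, nlat)
  } else NULL
  clm <- if ("cell_length" %in% names(nc$var)) {
    as.numeric(ncdf4::ncvar_get(nc, "cell_length"))
  } else NULL
  dims <- c(nlon, nlat, length(depth), length(times))
  getv <- function(nm) {
    a <- array(ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE), dims)
    a[is.na(a)] <- 0
    a
  }
  u <- getv("u"); v <- getv("v")
  w <- if ("w" %in% names(nc$var)) getv("w") else NULL
  if (!is.null(w) && all(w == 0)) w <- NULL
  if (!is.null(bathy)) bathy[!mask & bathy <= 0] <- max(depth) * 2
  grid <- grid_spec(lon, lat, depth, mask, bathy, clm)
  # enforce the zero-on-land contract on external files
  if (any(mask)) {
    land3 <- which(array(mask, dims))
    u[land3] <- 0; v[land3] <- 0
    if (!is.null(w)) w[land3] <- 0
  }
  list(field = velocity_field(times, u, v, w, grid), grid = grid)
}

#' Write MPA polygons to GeoJSON
#'
#' A FeatureCollection of Polygon features with properties \code{id},
#' \code{name}, \code{area_km2} and \code{ecoregion} (WGS84 lon/lat).
#'
#' @param mpas list of \code{\link{mpa_site}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_mpas_geojson <- function(mpas, path) {
  feats <- lapply(mpas, function(m) {
    list(type = "Feature",
         properties = list(id = m$id, name = m$name,
                           area_km2 = m$area_km2,
                           ecoregion = m$ecoregion),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(m$ring)),
                           function(r) as.numeric(m$ring[r, ])))))
  })
  json <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                           auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read MPA polygons from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of Polygon features.
#' @return list of \code{\link{mpa_site}}.
#' @export
read_mpas_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop_domain("expected a GeoJSON FeatureCollection")
  }
  lapply(gj$features, function(f) {
    if (f$geometry$type != "Polygon") {
      stop_domain("expected Polygon geometry, got ", f$geometry$type)
    }
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    p <- f$properties
    mpa_site(p$id, p$name, ring,
             area_km2 = if (is.null(p$area_km2)) NULL else p$area_km2,
             ecoregion = if (is.null(p$ecoregion)) NA_character_
                         else p$ecoregion)
  })
}

#' Write a connectivity matrix as CSV
#'
#' Rows are destination MPAs i, columns source MPAs j, header the MPA ids.
#'
#' @param cm a \code{\link{connectivity_matrix}} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_connectivity_csv <- function(cm, path) {
  m <- cm$c
  df <- data.frame(destination = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a connectivity matrix written by \code{\link{write_connectivity_csv}}
#'
#' Rebuilds the probability matrix; released counts are not stored in the CSV
#' and are taken from the \code{released} argument.
#'
#' @param path CSV file.
#' @param released per-source released counts (recycled).
#' @return a \code{\link{connectivity_matrix}} object.
#' @export
read_connectivity_csv <- function(path, released = 1) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  n <- nrow(m)
  rel <- rep(released, length.out = n)
  connectivity_matrix(counts = round(sweep(m, 2, rel, `*`)), released = rel)
}

#' Write a trajectory table as CSV
#'
#' One row per particle and recorded time with columns \code{particle_id},
#' \code{source_mpa}, \code{time_s}, \code{lon}, \code{lat}, \code{depth},
#' \code{status}. With \code{record = "final"} simulations only the final
#' snapshot is written; with \code{"daily"} the whole daily history is.
#'
#' @param traj a \code{\link{run_simulation}} result.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  dt <- traj$cfg$dt_s
  if (!is.null(traj$daily)) {
    tab <- data.frame(particle_id = traj$daily$id,
                      source_mpa = traj$particles$source[traj$daily$id],
                      time_s = traj$daily$step * dt,
                      lon = traj$daily$lon, lat = traj$daily$lat,
                      depth = traj$daily$depth,
                      status = c("active", "lost",
                                 "standstill")[traj$daily$status + 1L])
  } else {
    spd <- 86400 %/% dt
    end_step <- (traj$particles$release_day - 1L) * spd +
      traj$cfg$pld_days * spd
    tab <- data.frame(particle_id = traj$final$id,
                      source_mpa = traj$final$source,
                      time_s = end_step * dt,
                      lon = traj$final$lon, lat = traj$final$lat,
                      depth = traj$final$depth, status = traj$final$status)
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write the recruitment summary as JSON
#'
#' Connectance, the detection floor, and per-MPA local retention,
#' self-recruitment and subsidy fractions.
#'
#' @param cm a \code{\link{connectivity_matrix}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_recruitment_json <- function(cm, path) {
  rs <- recruitment_stats(cm)
  jsonlite::write_json(list(
    connectance = connectance(cm),
    detection_floor = cm$detection_floor,
    per_mpa = rs
  ), path, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}

#' Write the shelf-export fractions as CSV
#'
#' One row with the four export fractions (on shelf, open sea, within MPAs,
#' unseeded shelf) plus the particle accounting, optionally labelled with a
#' scenario name.
#'
#' @param summary an \code{\link{export_summary}} result.
#' @param path output CSV path.
#' @param scenario optional scenario label.
#' @return \code{path}, invisibly.
#' @export
write_export_csv <- function(summary, path, scenario = NA_character_) {
  utils::write.csv(data.frame(
    scenario = scenario,
    frac_on_shelf = summary$frac_on_shelf,
    frac_open_sea = summary$frac_open_sea,
    frac_in_mpas = summary$frac_in_mpas,
    frac_shelf_unseeded = summary$frac_shelf_unseeded,
    released = summary$released, lost = summary$lost
  ), path, row.names = FALSE)
  invisible(path)
}
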