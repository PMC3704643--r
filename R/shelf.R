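#' Continental-shelf mask
#'
#' Sea cells strictly shallower than 200 m -- the settlement-relevant coastal
#' zone. The boundary is strict: a 199.9 m cell is shelf, a 200.0 m cell is
#' not.
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param depth_limit_m shelf depth criterion (m, default 200).
#' @return logical \code{[nlon, nlat]} matrix.
#' @export
shelf_mask <- function(grid, depth_limit_m = 200) {
  grid$bathymetry > 0 & grid$bathymetry < depth_limit_m & !grid$land_mask
}

#' Larval export summary
#'
#' Bins non-lost final larval positions into grid cells and computes the
#' export statistics: the fraction of larvae ending on the continental shelf
#' versus the open sea, the fraction inside any MPA, and the area-weighted
#' fraction of shelf cells that received no larvae at all (unseeded shelf,
#' spherical cell areas with R = 6371 km). Larvae standing still at the coast
#' are scored into their (shelf) cell. Production weights are per source MPA:
#' uniform by default, or proportional to MPA surface area, normalized to the
#' same total, so the weighted abundance integrates to the number of non-lost
#' larvae.
#'
#' @param traj a \code{\link{trajectory_record}}.
#' @param grid a \code{\link{grid_spec}}.
#' @param mpas list of \code{\link{mpa_site}}.
#' @param production \code{"uniform"} or \code{"area"} (proportional to
#'   \code{area_km2}), or a numeric vector of per-MPA weights.
#' @return object of class \code{shelf_export_summary}: list with
#'   \code{abundance} (\code{[nlon, nlat]}), \code{frac_on_shelf},
#'   \code{frac_open_sea}, \code{frac_in_mpas}, \code{frac_shelf_unseeded},
#'   counts, and the shelf mask.
#' @export
export_summary <- function(traj, grid, mpas, production = "uniform") {
  n_mpa <- length(mpas)
  w <- if (is.character(production) && production == "uniform") {
    rep(1, n_mpa)
  } else if (is.character(production) && production == "area") {
    vapply(mpas, `[[`, numeric(1), "area_km2")
  } else as.numeric(production)
  if (length(w) != n_mpa || sum(w) <= 0) {
    stop_domain("production weights must be one positive-sum value per MPA")
  }
  w <- w * n_mpa / sum(w)   # normalized: mean weight 1

  fin <- traj$final
  keep <- fin$status != "lost"
  lon <- fin$lon[keep]; lat <- fin$lat[keep]; src <- fin$source[keep]
  ij <- grid_cell(grid, lon, lat)
  ok <- !is.na(ij$i) & !is.na(ij$j)
  cellidx <- (ij$j[ok] - 1L) * length(grid$lon) + ij$i[ok]
  wts <- w[src][ok]

  abundance <- matrix(0, length(grid$lon), length(grid$lat))
  tab <- rowsum(wts, cellidx)
  abundance[as.integer(rownames(tab))] <- tab[, 1]

  shelf <- shelf_mask(grid)
  on_shelf <- shelf[cellidx]
  n_on_shelf <- sum(on_shelf)
  n_nonlost <- sum(keep)

  settle <- assign_settlement(traj, mpas)
  n_in_mpas <- sum(settle$counts)

  lat_e <- grid$lat_edges; lon_e <- grid$lon_edges
  areas <- outer(diff(lon_e), rep(1, length(grid$lat))) * 0
  for (j in seq_along(grid$lat)) {
    areas[, j] <- cell_area_km2(lon_e[-length(lon_e)], lon_e[-1],
                                lat_e[j], lat_e[j + 1])
  }
  shelf_area <- sum(areas[shelf])
  unseeded <- shelf & abundance == 0
  frac_unseeded <- if (shelf_area > 0) sum(areas[unseeded]) / shelf_area
                   else NA_real_

  structure(list(
    abundance = abundance, shelf = shelf, cell_area_km2 = areas,
    released = traj$released, lost = traj$lost,
    n_non_lost = n_nonlost, n_on_shelf = n_on_shelf,
    n_open_sea = n_nonlost - n_on_shelf, n_in_mpas = n_in_mpas,
    frac_on_shelf = if (n_nonlost > 0) n_on_shelf / n_nonlost else NA_real_,
    frac_open_sea = if (n_nonlost > 0) 1 - n_on_shelf / n_nonlost else NA_real_,
    frac_in_mpas = if (n_nonlost > 0) n_in_mpas / n_nonlost else NA_real_,
    frac_shelf_unseeded = frac_unseeded,
    production = w
  ), class = "shelf_export_summary")
}

#' @export
print.shelf_export_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "shelf_export_summary: %.1f%% on shelf, %.1f%% open sea, ",
    "%.1f%% in MPAs, %.1f%% of shelf unseeded\n"),
    100 * x$frac_on_shelf, 100 * x$frac_open_sea, 100 * x$frac_in_mpas,
    100 * x$frac_shelf_unseeded))
  invisible(x)
}

#' Write the larval-abundance map
#'
#' Writes the gridded abundance as a NetCDF layer \code{larval_abundance}
#' and, optionally, an image with shelf cells colored by abundance and
#' unseeded shelf in a reserved color.
#'
#' @param summary a \code{\link{export_summary}} result.
#' @param grid the \code{\link{grid_spec}}.
#' @param path NetCDF output path.
#' @param png_path optional image path (requires a PNG-capable device).
#' @return \code{path}, invisibly.
#' @export
abundance_map_write <- function(summary, grid, path, png_path = NULL) {
  dl <- ncdf4::ncdim_def("lon", "degrees_east", grid$lon)
  dp <- ncdf4::ncdim_def("lat", "degrees_north", grid$lat)
  va <- ncdf4::ncvar_def("larval_abundance", "1", list(dl, dp),
                         prec = "double")
  vs <- ncdf4::ncvar_def("shelf", "1", list(dl, dp), prec = "integer")
  nc <- ncdf4::nc_create(path, list(va, vs))
  ncdf4::ncvar_put(nc, va, summary$abundance)
  ncdf4::ncvar_put(nc, vs, summary$shelf * 1L)
  ncdf4::nc_close(nc)
  if (!is.null(png_path)) {
    ok <- tryCatch({
      grDevices::png(png_path, width = 900, height = 500)
      on.exit(grDevices::dev.off(), add = TRUE)
      z <- summary$abundance
      z[!summary$shelf] <- NA          # map shows shelf cells only
      zc <- log10(z + 1)
      graphics::image(grid$lon, grid$lat, zc,
                      col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                      xlab = "lon", ylab = "lat",
                      main = "Larval abundance on the continental shelf")
      un <- which(summary$shelf & summary$abundance == 0, arr.ind = TRUE)
      if (nrow(un)) graphics::points(grid$lon[un[, 1]], grid$lat[un[, 2]],
                                     pch = 15, cex = 0.3, col = "grey60")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) warning("could not render PNG map (no graphics device?)")
  }
  invisible(path)
}

#' Read back an abundance layer written by \code{\link{abundance_map_write}}
#'
#' @param path NetCDF file.
#' @return list with \code{abundance} matrix and \code{shelf} mask.
#' @export
abundance_map_read <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  list(abundance = ncdf4::ncvar_get(nc, "larval_abundance"),
       shelf = ncdf4::ncvar_get(nc, "shelf") > 0)
}
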