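#' Configuration of a synthetic dispersal domain
#'
#' Describes a Mediterranean-like test domain: a regular 1/12-degree lon/lat
#' grid, a land band along one edge with a continental shelf (< 200 m) of
#' configurable width ramping to deep water, a set of rectangular MPA polygons
#' sitting on the shelf, and an analytic flow. Flow kinds:
#' \describe{
#'   \item{uniform}{constant horizontal current \code{(amplitude, 0)} rotated
#'     by \code{direction_deg}.}
#'   \item{solid_rotation}{rigid rotation about the domain center with angular
#'     speed \code{2*pi/period_days}.}
#'   \item{double_gyre}{two counter-rotating gyres from the streamfunction
#'     \code{psi = A sin(pi f(x)) sin(pi y / Ly)}; with \code{gyre_eps > 0}
#'     the inter-gyre boundary oscillates in time
#'     (\code{f = a(t) x^2 + b(t) x}, the standard time-periodic double-gyre
#'     test flow), producing chaotic stirring like basin eddies; velocities
#'     are centered differences of psi so the discrete flow is exactly
#'     non-divergent at every snapshot.}
#'   \item{boundary_jet}{an along-coast current of peak speed \code{amplitude}
#'     decaying offshore with e-folding scale \code{jet_width_km}.}
#' }
#' All flows can be surface-intensified: speeds are multiplied by
#' \code{exp(-depth / depth_decay_m)} so a diel vertical migrant at 50 m sits
#' in weaker currents than a surface drifter, and optionally modulated
#' seasonally.
#'
#' @param lon_range,lat_range domain bounds in degrees (c(min, max)).
#' @param resolution_deg grid spacing in degrees (default 1/12, eddy-permitting
#'   basin-model resolution).
#' @param depth_levels layer-midpoint depths in meters, positive down.
#' @param flow one of \code{"uniform"}, \code{"solid_rotation"},
#'   \code{"double_gyre"}, \code{"boundary_jet"}.
#' @param amplitude flow amplitude in m/s (basin currents are ~0.1-0.5 m/s).
#' @param direction_deg direction of the uniform flow (0 = eastward, CCW).
#' @param period_days rotation period for \code{solid_rotation}.
#' @param gyre_lon_span,gyre_lat_span gyre box size in degrees (NULL = domain).
#' @param gyre_lat_offset_km southern offset of the gyre box from the coast
#'   (km): the gyre circulation is confined offshore of this line (zero
#'   streamfunction inshore), leaving the coastal strip to the jet and the
#'   sub-grid random walk, as basin-interior gyres do not penetrate a shallow
#'   shelf.
#' @param gyre_eps amplitude of the periodic inter-gyre boundary oscillation
#'   (0 = steady gyres; 0.25 is the classical chaotic-stirring value).
#' @param gyre_period_days period of the oscillation (days).
#' @param jet_width_km offshore e-folding width of the boundary jet.
#' @param depth_decay_m e-folding depth of the surface intensification;
#'   \code{Inf} gives a depth-uniform flow.
#' @param seasonal_amp relative seasonal modulation of the amplitude
#'   (0 = steady); day \code{d} is scaled by
#'   \code{1 + seasonal_amp * cos(2*pi*(d - seasonal_peak_day)/365)}.
#' @param seasonal_peak_day day of peak amplitude.
#' @param coast_edge edge carrying the land band: "south", "north", "west",
#'   "east", "basin" (land on all four edges -- a closed Mediterranean-like
#'   basin with its shelf along the southern coast), or "none".
#' @param jet_reversal_amp relative amplitude r of a periodic reversal of the
#'   boundary jet (wind-driven coastal current reversals): the jet is scaled
#'   by \code{(1 - r) + r * mean(cos(2*pi*(day - 0.5)/P_i))} over the periods
#'   \code{P_i}, so r = 0 is steady and larger r swings the jet between full
#'   strength and partial upstream flow.
#' @param jet_reversal_period_days period(s) of the jet reversal cycle
#'   (days); two incommensurate periods (the default) emulate episodic,
#'   non-monochromatic wind forcing.
#' @param land_width_cells width of the land band in cells.
#' @param shelf_width_km width of the continental shelf (< 200 m).
#' @param deep_depth_m open-ocean bathymetry beyond the shelf break.
#' @param n_mpas number of MPA polygons to place on the shelf.
#' @param mpa_size_km side length of each (roughly square) MPA.
#' @param mpa_spacing_km along-coast spacing between MPA centroids; either a
#'   scalar (even spacing) or a vector of successive gaps (recycled to
#'   n_mpas - 1), allowing clustered layouts with large inter-group gaps
#'   like the real Mediterranean MPA system.
#' @param seed RNG seed used by the generators.
#' @return an object of class \code{synth_domain_config}.
#' @export
synth_domain_config <- function(lon_range = c(0, 10), lat_range = c(38, 42),
                                resolution_deg = 1 / 12,
                                depth_levels = c(0.5, 10, 30, 50, 100, 300),
                                flow = c("double_gyre", "uniform",
                                         "solid_rotation", "boundary_jet"),
                                amplitude = 0.2, direction_deg = 0,
                                period_days = 30,
                                gyre_lon_span = NULL, gyre_lat_span = NULL,
                                gyre_lat_offset_km = 0,
                                gyre_eps = 0.25, gyre_period_days = 10,
                                jet_width_km = 30,
                                jet_reversal_amp = 0,
                                jet_reversal_period_days = c(9.5, 16),
                                depth_decay_m = 40,
                                seasonal_amp = 0, seasonal_peak_day = 1,
                                coast_edge = c("south", "north", "west",
                                               "east", "basin", "none"),
                                land_width_cells = 3,
                                shelf_width_km = 40, deep_depth_m = 2500,
                                n_mpas = 12, mpa_size_km = 15,
                                mpa_spacing_km = 60,
                                seed = 1L) {
  flow <- match.arg(flow)
  coast_edge <- match.arg(coast_edge)
  nlon <- floor(diff(lon_range) / resolution_deg)
  nlat <- floor(diff(lat_range) / resolution_deg)
  if (nlon < 10 || nlat < 10) {
    stop_domain("resolution must yield at least a 10 x 10 grid")
  }
  if (amplitude > 2) {
    warning("amplitude > 2 m/s is unrealistic for basin-scale currents")
  }
  structure(list(
    lon_range = lon_range, lat_range = lat_range,
    resolution_deg = resolution_deg, depth_levels = depth_levels,
    flow = flow, amplitude = amplitude, direction_deg = direction_deg,
    period_days = period_days,
    gyre_lon_span = gyre_lon_span, gyre_lat_span = gyre_lat_span,
    gyre_lat_offset_km = gyre_lat_offset_km,
    gyre_eps = gyre_eps, gyre_period_days = gyre_period_days,
    jet_width_km = jet_width_km, jet_reversal_amp = jet_reversal_amp,
    jet_reversal_period_days = jet_reversal_period_days,
    depth_decay_m = depth_decay_m,
    seasonal_amp = seasonal_amp, seasonal_peak_day = seasonal_peak_day,
    coast_edge = coast_edge, land_width_cells = land_width_cells,
    shelf_width_km = shelf_width_km, deep_depth_m = deep_depth_m,
    n_mpas = n_mpas, mpa_size_km = mpa_size_km,
    mpa_spacing_km = mpa_spacing_km, seed = as.integer(seed)
  ), class = "synth_domain_config")
}

#' Synthetic coastline, bathymetry and MPA polygons
#'
#' Builds the grid for a configured domain: a land band along the chosen
#' edge, bathymetry ramping linearly from ~0 at the coast to 200 m across the
#' shelf and on to \code{deep_depth_m} beyond the shelf break, and
#' \code{n_mpas} rectangular MPA polygons placed over the shelf at the
#' configured along-coast spacing.
#'
#' @param cfg a \code{\link{synth_domain_config}}.
#' @return list with elements \code{grid} (a \code{\link{grid_spec}}) and
#'   \code{mpas} (list of \code{\link{mpa_site}}).
#' @export
synth_coast_and_mpas <- function(cfg) {
  res <- cfg$resolution_deg
  lon <- seq(cfg$lon_range[1] + res / 2, cfg$lon_range[2] - res / 2, by = res)
  lat <- seq(cfg$lat_range[1] + res / 2, cfg$lat_range[2] - res / 2, by = res)
  nlon <- length(lon); nlat <- length(lat)
  midlat <- mean(cfg$lat_range)
  km_per_deg_lat <- M_PER_DEG / 1000
  km_per_deg_lon <- km_per_deg_lat * cos(midlat * pi / 180)

  land <- matrix(FALSE, nlon, nlat)
  # distance from the coastline (km), per cell, along the offshore direction
  offshore_km <- matrix(Inf, nlon, nlat)
  lw <- cfg$land_width_cells
  if (cfg$coast_edge %in% c("south", "basin")) {
    land[, seq_len(lw)] <- TRUE
    coast_lat <- lat[lw] + res / 2
    offshore_km <- matrix(rep((lat - coast_lat) * km_per_deg_lat, each = nlon),
                          nlon, nlat)
    if (cfg$coast_edge == "basin") {
      # closed basin: land frame on the remaining three edges; the shelf
      # stays along the southern coast, other coasts drop steeply
      land[seq_len(lw), ] <- TRUE
      land[nlon - seq_len(lw) + 1L, ] <- TRUE
      land[, nlat - seq_len(lw) + 1L] <- TRUE
    }
  } else if (cfg$coast_edge == "north") {
    land[, nlat - seq_len(lw) + 1L] <- TRUE
    coast_lat <- lat[nlat - lw] + res / 2
    offshore_km <- matrix(rep((coast_lat - lat) * km_per_deg_lat, each = nlon),
                          nlon, nlat)
  } else if (cfg$coast_edge == "west") {
    land[seq_len(lw), ] <- TRUE
    coast_lon <- lon[lw] + res / 2
    offshore_km <- matrix((lon - coast_lon) * km_per_deg_lon, nlon, nlat)
  } else if (cfg$coast_edge == "east") {
    land[nlon - seq_len(lw) + 1L, ] <- TRUE
    coast_lon <- lon[nlon - lw] + res / 2
    offshore_km <- matrix((coast_lon - lon) * km_per_deg_lon, nlon, nlat)
  }

  cell_km <- res * km_per_deg_lat
  bathy <- matrix(cfg$deep_depth_m, nlon, nlat)
  sea <- !land
  if (cfg$coast_edge != "none") {
    d <- pmax(offshore_km, cell_km / 2)  # first sea row is already wet
    shelf_w <- max(cfg$shelf_width_km, 0)
    on_shelf <- d <= shelf_w
    # linear ramp 0 -> 200 m across the shelf, then 200 -> deep over 3 widths
    ramp <- ifelse(on_shelf, 200 * d / max(shelf_w, cell_km),
                   pmin(cfg$deep_depth_m,
                        200 + (d - shelf_w) / (3 * max(shelf_w, cell_km)) *
                          (cfg$deep_depth_m - 200)))
    bathy[sea] <- pmax(ramp[sea], 1)
  }
  grid <- grid_spec(lon, lat, cfg$depth_levels, land, bathy)

  mpas <- list()
  if (cfg$n_mpas > 0) {
    if (cfg$coast_edge %in% c("west", "east")) {
      stop_domain("MPA placement implemented for south/north coasts")
    }
    if (cfg$coast_edge == "none") {
      # open-ocean domain: place MPAs along the domain mid-latitude
      base_lat <- midlat
    } else if (cfg$coast_edge %in% c("south", "basin")) {
      base_lat <- lat[lw] + res / 2   # polygons hug the coastline
    } else {
      base_lat <- lat[nlat - lw] - res / 2
    }
    size_deg_lat <- cfg$mpa_size_km / km_per_deg_lat
    size_deg_lon <- cfg$mpa_size_km / km_per_deg_lon
    gaps_km <- rep(cfg$mpa_spacing_km, length.out = max(cfg$n_mpas - 1, 1))
    offsets_deg <- cumsum(c(0, gaps_km)) / km_per_deg_lon
    lat0 <- if (cfg$coast_edge == "north") base_lat - size_deg_lat else base_lat
    side_land <- if (cfg$coast_edge %in% c("basin", "west", "east"))
      cfg$land_width_cells * res else 0
    margin <- side_land + 2 * res + size_deg_lon
    span_needed <- offsets_deg[cfg$n_mpas]
    if (span_needed > diff(cfg$lon_range) - 2 * margin) {
      stop_domain("domain too narrow for ", cfg$n_mpas,
                  " MPAs at the configured spacing")
    }
    start_lon <- cfg$lon_range[1] + margin
    for (k in seq_len(cfg$n_mpas)) {
      x0 <- start_lon + offsets_deg[k]
      ring <- cbind(lon = c(x0, x0 + size_deg_lon, x0 + size_deg_lon, x0, x0),
                    lat = c(lat0, lat0, lat0 + size_deg_lat,
                            lat0 + size_deg_lat, lat0))
      ctr <- c(x0 + size_deg_lon / 2, lat0 + size_deg_lat / 2)
      if (is_land_at(grid, ctr[1], ctr[2])) {
        stop_domain("MPA ", k, " would sit entirely on land")
      }
      mpas[[k]] <- mpa_site(k, sprintf("MPA-%02d", k), ring)
    }
  }
  list(grid = grid, mpas = mpas)
}

#' Synthetic daily current fields
#'
#' Generates \code{n_days} daily velocity snapshots of the configured analytic
#' flow on the configured grid, zeroed on land cells, with \code{w = 0}.
#'
#' The phases of the periodic components (gyre oscillation, jet reversal) are
#' drawn from \code{cfg$seed}, so different seeds give independent
#' realizations of the same climatological flow -- the synthetic analogue of
#' pooling different years of an ocean hindcast.
#'
#' @param cfg a \code{\link{synth_domain_config}}.
#' @param n_days number of daily snapshots.
#' @param grid optional pre-built \code{\link{grid_spec}} (from
#'   \code{\link{synth_coast_and_mpas}}); regenerated from \code{cfg} if NULL.
#' @return a \code{\link{velocity_field}}.
#' @export
synth_flow <- function(cfg, n_days, grid = NULL) {
  if (is.null(grid)) grid <- synth_coast_and_mpas(cfg)$grid
  phases <- local({
    set.seed(cfg$seed)
    list(gyre = stats::runif(1, 0, 2 * pi),
         jet = stats::runif(length(cfg$jet_reversal_period_days), 0, 2 * pi))
  })
  lon <- grid$lon; lat <- grid$lat
  nlon <- length(lon); nlat <- length(lat); nz <- length(grid$depth)
  midlat <- mean(range(lat))
  mx <- M_PER_DEG * cos(midlat * pi / 180)   # meters per degree lon
  my <- M_PER_DEG                            # meters per degree lat
  A <- cfg$amplitude

  u2 <- matrix(0, nlon, nlat); v2 <- matrix(0, nlon, nlat)
  if (cfg$flow == "uniform") {
    th <- cfg$direction_deg * pi / 180
    u2[] <- A * cos(th); v2[] <- A * sin(th)
  } else if (cfg$flow == "solid_rotation") {
    omega <- 2 * pi / (cfg$period_days * 86400)
    ctr <- c(mean(range(lon)), mean(range(lat)))
    x <- outer((lon - ctr[1]) * mx, rep(1, nlat))
    y <- outer(rep(1, nlon), (lat - ctr[2]) * my)
    u2 <- -omega * y; v2 <- omega * x
  } else if (cfg$flow == "boundary_jet") {
    if (cfg$coast_edge %in% c("south", "north", "basin")) {
      lw <- cfg$land_width_cells
      coast_lat <- if (cfg$coast_edge == "north")
                     lat[nlat - lw] - cfg$resolution_deg / 2
                   else lat[lw] + cfg$resolution_deg / 2
      dist_km <- abs(outer(rep(1, nlon), (lat - coast_lat)) * my / 1000)
      u2 <- A * exp(-dist_km / cfg$jet_width_km)
    } else {
      stop_domain("boundary_jet requires a south or north coast")
    }
  }
  # the (possibly time-periodic) double gyre is rebuilt per day
  gyre_uv <- NULL
  if (cfg$flow == "double_gyre") {
    # two side-by-side counter-rotating gyres across the domain by default
    Lx <- if (is.null(cfg$gyre_lon_span)) diff(range(lon)) / 2 else cfg$gyre_lon_span
    lat_south <- lat[1] + cfg$gyre_lat_offset_km * 1000 / my
    Ly <- if (is.null(cfg$gyre_lat_span)) max(lat) - lat_south
          else cfg$gyre_lat_span
    xd <- (lon - lon[1]) / (2 * Lx)   # normalized 0..1 over the gyre pair
    yd <- pmax(lat - lat_south, 0) / Ly   # psi = 0 inshore of the gyre box
    dx <- mean(diff(lon)) * mx; dy <- mean(diff(lat)) * my
    iw <- pmax(seq_len(nlon) - 1L, 1L); ie <- pmin(seq_len(nlon) + 1L, nlon)
    js <- pmax(seq_len(nlat) - 1L, 1L); jn <- pmin(seq_len(nlat) + 1L, nlat)
    ddy <- outer(rep(1, nlon), (jn - js) * dy)
    ddx <- outer((ie - iw) * dx, rep(1, nlat))
    psi0 <- A * (Ly * my) / pi  # scales peak |u| to ~A
    gyre_uv <- function(day) {
      # time-periodic inter-gyre boundary (classical chaotic test flow):
      # f(x, t) = a(t) x^2 + b(t) x on x in [0, 2], steady when gyre_eps = 0
      e <- cfg$gyre_eps * sin(2 * pi * (day - 0.5) / cfg$gyre_period_days +
                              phases$gyre)
      x2 <- 2 * xd
      fx <- e * x2^2 + (1 - 2 * e) * x2
      # streamfunction on grid nodes; velocities are centered differences of
      # psi, so the centered-difference divergence vanishes identically in
      # the interior (the discrete analogue of non-divergence)
      psi <- psi0 * outer(sin(pi * fx), sin(pi * yd))
      uu <- -(psi[, jn] - psi[, js]) / ddy
      vv <- (psi[ie, ] - psi[iw, ]) / ddx
      uu[grid$land_mask] <- 0; vv[grid$land_mask] <- 0
      list(u = uu, v = vv)
    }
  }
  u2[grid$land_mask] <- 0; v2[grid$land_mask] <- 0

  zfac <- if (is.finite(cfg$depth_decay_m)) exp(-grid$depth / cfg$depth_decay_m)
          else rep(1, nz)
  day_fac <- 1 + cfg$seasonal_amp *
    cos(2 * pi * (seq_len(n_days) - cfg$seasonal_peak_day) / 365)
  if (cfg$flow == "boundary_jet" && cfg$jet_reversal_amp > 0) {
    r <- cfg$jet_reversal_amp
    ph <- rowMeans(vapply(seq_along(cfg$jet_reversal_period_days), function(i) {
      cos(2 * pi * (seq_len(n_days) - 0.5) / cfg$jet_reversal_period_days[i] +
          phases$jet[i])
    }, numeric(n_days)))
    day_fac <- day_fac * ((1 - r) + r * ph)
  }

  u <- array(0, c(nlon, nlat, nz, n_days))
  v <- array(0, c(nlon, nlat, nz, n_days))
  for (t in seq_len(n_days)) {
    if (!is.null(gyre_uv)) {
      g <- gyre_uv(t)
      u2 <- g$u; v2 <- g$v
    }
    for (k in seq_len(nz)) {
      u[, , k, t] <- u2 * zfac[k] * day_fac[t]
      v[, , k, t] <- v2 * zfac[k] * day_fac[t]
    }
  }
  velocity_field(seq_len(n_days), u, v, NULL, grid)
}

#' Superpose two velocity fields
#'
#' Adds the components of two fields on the same grid and day set --
#' composite circulations (e.g. basin gyres plus a coastal jet) are built by
#' superposition of the analytic ingredients.
#'
#' @param a,b \code{\link{velocity_field}} objects on the same grid.
#' @return a \code{\link{velocity_field}}.
#' @export
add_fields <- function(a, b) {
  if (!identical(dim(a$u), dim(b$u))) stop_domain("fields differ in shape")
  w <- if (is.null(a$w) && is.null(b$w)) NULL else {
    (if (is.null(a$w)) 0 else a$w) + (if (is.null(b$w)) 0 else b$w)
  }
  structure(list(times = a$times, u = a$u + b$u, v = a$v + b$v, w = w),
            class = "velocity_field")
}

#' Reference synthetic study domain: two gyres over a coastal jet
#'
#' The package's standard test-bed for sensitivity analyses: a 10 x 4 degree
#' Mediterranean-like basin at 1/12 degree with a southern coast, a 40 km
#' continental shelf, \code{n_mpas} MPAs spaced along the shelf, and a
#' surface-intensified circulation superposing two counter-rotating basin
#' gyres (0.1 m/s, with the classical time-periodic inter-gyre oscillation
#' that stirs chaotically like basin eddies) on an along-coast jet (0.2 m/s
#' peak, 30 km e-folding width). Peak speeds stay well under 0.5 m/s, so the
#' default 7200 s time step is admissible for the ~8 km cells.
#'
#' @param n_days days of daily currents to generate.
#' @param n_mpas number of MPAs on the shelf.
#' @param mpa_spacing_km successive along-coast gaps between MPA centroids
#'   (recycled); the default groups the MPAs into clusters of four spaced
#'   35 km apart, separated by 110 km gaps -- dense MPA groups with large
#'   unprotected stretches between them, as in the Mediterranean system.
#' @param seed generator seed.
#' @return list with \code{grid}, \code{mpas}, \code{field}, and the two
#'   \code{\link{synth_domain_config}}s used (\code{cfg_gyre},
#'   \code{cfg_jet}).
#' @export
gyre_jet_domain <- function(n_days = 70, n_mpas = 12,
                            mpa_spacing_km = c(35, 35, 35, 110),
                            seed = 1L) {
  cfg_jet <- synth_domain_config(
    lon_range = c(0, 10), lat_range = c(38, 42), flow = "boundary_jet",
    amplitude = 0.2, jet_width_km = 30, depth_decay_m = 40,
    jet_reversal_amp = 0.75,
    coast_edge = "basin", shelf_width_km = 25,
    n_mpas = n_mpas, mpa_size_km = 15, mpa_spacing_km = mpa_spacing_km,
    seed = seed)
  cfg_gyre <- cfg_jet
  cfg_gyre$flow <- "double_gyre"
  cfg_gyre$amplitude <- 0.05  # interior gyres weaker than the boundary jet
  cfg_gyre$gyre_lat_offset_km <- 35  # gyres stay off the 25 km shelf
  dom <- synth_coast_and_mpas(cfg_jet)
  field <- add_fields(synth_flow(cfg_jet, n_days, dom$grid),
                      synth_flow(cfg_gyre, n_days, dom$grid))
  list(grid = dom$grid, mpas = dom$mpas, field = field,
       cfg_gyre = cfg_gyre, cfg_jet = cfg_jet)
}
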