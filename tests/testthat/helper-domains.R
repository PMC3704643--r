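# Small fixture domains built in code at test time.

# Deep, all-sea domain with a single small MPA in the middle: for advection
# and diffusion oracles where no coast must interfere.
open_ocean_fixture <- function(lon_range = c(0, 10), lat_range = c(38, 42),
                               res = 1 / 12, depth = c(0.5, 10, 30, 50, 100),
                               mpa_size_deg = 0.1) {
  lon <- seq(lon_range[1] + res / 2, lon_range[2] - res / 2, by = res)
  lat <- seq(lat_range[1] + res / 2, lat_range[2] - res / 2, by = res)
  grid <- grid_spec(lon, lat, depth)
  ctr <- c(mean(lon_range), mean(lat_range))
  h <- mpa_size_deg / 2
  ring <- cbind(ctr[1] + c(-h, h, h, -h, -h), ctr[2] + c(-h, -h, h, h, -h))
  list(grid = grid, mpas = list(mpa_site(1L, "center", ring)))
}

# Constant uniform flow on a grid, depth-uniform (no shear).
uniform_field <- function(grid, n_days, u = 0.1, v = 0) {
  nlon <- length(grid$lon); nlat <- length(grid$lat); nz <- length(grid$depth)
  ua <- array(u, c(nlon, nlat, nz, n_days))
  va <- array(v, c(nlon, nlat, nz, n_days))
  land3 <- which(array(grid$land_mask, dim(ua)))
  ua[land3] <- 0; va[land3] <- 0
  velocity_field(seq_len(n_days), ua, va, NULL, grid)
}

# Tiny coastal domain (south coast) for settlement/standstill/shelf tests.
coastal_fixture <- function(n_mpas = 3, flow = "uniform", amplitude = 0,
                            spacing = 60, shelf_width_km = 40, seed = 1) {
  cfg <- synth_domain_config(
    lon_range = c(0, 5), lat_range = c(39, 41), flow = flow,
    amplitude = amplitude, coast_edge = "south",
    shelf_width_km = shelf_width_km, n_mpas = n_mpas,
    mpa_size_km = 15, mpa_spacing_km = spacing, seed = seed)
  dom <- synth_coast_and_mpas(cfg)
  list(cfg = cfg, grid = dom$grid, mpas = dom$mpas)
}

# A trajectory_record built by hand from final positions, for unit tests of
# the settlement/statistics layer without running the tracker.
fake_traj <- function(lon0, lat0, lon1, lat1, source, status = "active",
                      depth = 0.2) {
  n <- length(lon1)
  structure(list(
    particles = data.frame(id = seq_len(n), source = source, event = 1L,
                           release_day = 1L, lon = lon0, lat = lat0,
                           depth = depth),
    final = data.frame(id = seq_len(n), source = source, lon = lon1,
                       lat = lat1, depth = depth,
                       status = rep(status, length.out = n)),
    released = n,
    lost = sum(rep(status, length.out = n) == "lost"),
    standstill = sum(rep(status, length.out = n) == "standstill"),
    daily = NULL, kh = 0,
    cfg = sim_config(larvae_per_event = 1)
  ), class = "trajectory_record")
}
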