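test_that("grid_spec validates axes, mask and bathymetry", {
  expect_error(grid_spec(c(1, 1, 2), 1:3), "increasing")
  expect_error(grid_spec(1:3, 1:3, depth = c(5, 2)), "increasing")
  g <- grid_spec(1:4, 1:3, depth = c(0.5, 10))
  expect_s3_class(g, "grid_spec")
  expect_equal(dim(g$land_mask), c(4L, 3L))
  # land cells force zero bathymetry
  lm <- matrix(FALSE, 4, 3); lm[1, ] <- TRUE
  b <- matrix(100, 4, 3)
  g2 <- grid_spec(1:4, 1:3, land_mask = lm, bathymetry = b)
  expect_true(all(g2$bathymetry[1, ] == 0))
  expect_error(grid_spec(1:4, 1:3, land_mask = lm,
                         bathymetry = matrix(0, 4, 3)), "bathymetry")
})

test_that("velocity_field rejects mismatched shapes and velocity on land", {
  g <- grid_spec(1:4, 1:3, depth = 0.5)
  u <- array(0.1, c(4, 3, 1, 2)); v <- array(0, c(4, 3, 1, 2))
  expect_s3_class(velocity_field(1:2, u, v, NULL, g), "velocity_field")
  expect_error(velocity_field(1:3, u, v, NULL, g), "dim")
  lm <- matrix(FALSE, 4, 3); lm[2, 2] <- TRUE
  gl <- grid_spec(1:4, 1:3, land_mask = lm)
  expect_error(velocity_field(1:2, u, v, NULL, gl), "zero on land")
})

test_that("uniform synthetic flow has the configured constant velocity at sea", {
  cfg <- synth_domain_config(flow = "uniform", amplitude = 0.2,
                             depth_decay_m = Inf, n_mpas = 0)
  dom <- synth_coast_and_mpas(cfg)
  f <- synth_flow(cfg, 2, dom$grid)
  sea3 <- !array(dom$grid$land_mask, dim(f$u))
  expect_true(all(f$u[sea3] == 0.2))
  expect_true(all(f$v[sea3] == 0))
  expect_true(all(f$u[!sea3] == 0))
})

test_that("solid rotation speed equals omega * r at sampled cells", {
  cfg <- synth_domain_config(flow = "solid_rotation", period_days = 30,
                             coast_edge = "none", depth_decay_m = Inf,
                             n_mpas = 0, lat_range = c(-2, 2))
  dom <- synth_coast_and_mpas(cfg)
  f <- synth_flow(cfg, 1, dom$grid)
  g <- dom$grid
  omega <- 2 * pi / (30 * 86400)
  ctr <- c(mean(range(g$lon)), mean(range(g$lat)))
  mx <- 2 * pi * 6371000 / 360 * cos(mean(range(g$lat)) * pi / 180)
  my <- 2 * pi * 6371000 / 360
  for (idx in list(c(10L, 10L), c(60L, 24L), c(100L, 40L))) {
    x <- (g$lon[idx[1]] - ctr[1]) * mx
    y <- (g$lat[idx[2]] - ctr[2]) * my
    speed <- sqrt(f$u[idx[1], idx[2], 1, 1]^2 + f$v[idx[1], idx[2], 1, 1]^2)
    expect_equal(speed, omega * sqrt(x^2 + y^2), tolerance = 1e-12)
  }
})

test_that("double gyre is discretely non-divergent and closed at the box edges", {
  cfg <- synth_domain_config(flow = "double_gyre", amplitude = 0.2,
                             coast_edge = "none", depth_decay_m = Inf,
                             gyre_eps = 0.25, n_mpas = 0)
  dom <- synth_coast_and_mpas(cfg)
  f <- synth_flow(cfg, 3, dom$grid)
  g <- dom$grid
  nlon <- length(g$lon); nlat <- length(g$lat)
  mx <- 2 * pi * 6371000 / 360 * cos(mean(range(g$lat)) * pi / 180)
  my <- 2 * pi * 6371000 / 360
  dx <- mean(diff(g$lon)) * mx; dy <- mean(diff(g$lat)) * my
  for (day in 1:3) {
    u <- f$u[, , 1, day]; v <- f$v[, , 1, day]
    # no flow through the outer gyre-box boundary (sin terms vanish)
    expect_lt(max(abs(u[1, ])), 1e-12)
    expect_lt(max(abs(v[, 1])), 1e-12)
    expect_lt(max(abs(v[, nlat])), 1e-12)
    i <- 2:(nlon - 1); j <- 2:(nlat - 1)
    div <- (u[i + 1, j] - u[i - 1, j]) / (2 * dx) +
           (v[i, j + 1] - v[i, j - 1]) / (2 * dy)
    expect_lt(max(abs(div)), 1e-6 * max(sqrt(u^2 + v^2)))
  }
})

test_that("synthetic coast places a shelf and correctly spaced MPAs", {
  cfg <- synth_domain_config(lon_range = c(0, 8), lat_range = c(38, 42),
                             coast_edge = "south", shelf_width_km = 50,
                             n_mpas = 2, mpa_size_km = 15,
                             mpa_spacing_km = 500)
  dom <- synth_coast_and_mpas(cfg)
  c1 <- colMeans(dom$mpas[[1]]$ring[1:4, ])
  c2 <- colMeans(dom$mpas[[2]]$ring[1:4, ])
  d <- great_circle_km(c1[1], c1[2], c2[1], c2[2])
  expect_lt(abs(d - 500) / 500, 0.05)
  # shelf mask width matches the configured shelf width to within one cell
  sm <- shelf_mask(dom$grid)
  shelf_rows <- which(apply(sm, 2, any))
  width_km <- length(shelf_rows) * mean(diff(dom$grid$lat)) * 111.195
  expect_lt(abs(width_km - 50), 2 * mean(diff(dom$grid$lat)) * 111.195)
})

test_that("many small MPAs round-trip through GeoJSON with ids preserved", {
  cfg <- synth_domain_config(lon_range = c(0, 42), lat_range = c(38, 42),
                             coast_edge = "south", n_mpas = 115,
                             mpa_size_km = 10, mpa_spacing_km = 30)
  dom <- synth_coast_and_mpas(cfg)
  expect_length(dom$mpas, 115)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_mpas_geojson(dom$mpas, path)
  back <- read_mpas_geojson(path)
  expect_length(back, 115)
  expect_identical(vapply(back, `[[`, integer(1), "id"), 1:115)
  expect_equal(back[[7]]$ring, dom$mpas[[7]]$ring, ignore_attr = TRUE)
  expect_equal(back[[7]]$area_km2, dom$mpas[[7]]$area_km2)
})

test_that("velocity fields round-trip bit-identically through NetCDF", {
  cfg <- synth_domain_config(lon_range = c(0, 2.5), lat_range = c(39, 40),
                             flow = "double_gyre", n_mpas = 0)
  dom <- synth_coast_and_mpas(cfg)
  f <- synth_flow(cfg, 4, dom$grid)
  path <- withr::local_tempfile(fileext = ".nc")
  write_velocity_field(f, dom$grid, path)
  back <- read_velocity_field(path)
  expect_identical(back$field$u, f$u)
  expect_identical(back$field$v, f$v)
  expect_null(back$field$w)           # all-zero w collapses to NULL
  expect_equal(back$grid$lon, dom$grid$lon)
  expect_equal(back$grid$bathymetry, dom$grid$bathymetry)
  expect_equal(back$grid$land_mask, dom$grid$land_mask)
  expect_equal(back$grid$cell_length_m, dom$grid$cell_length_m)
})

test_that("NetCDF reader reports missing variables and dimensions by name", {
  path <- withr::local_tempfile(fileext = ".nc")
  dl <- ncdf4::ncdim_def("lon", "degrees_east", 1:5)
  dp <- ncdf4::ncdim_def("lat", "degrees_north", 1:4)
  dz <- ncdf4::ncdim_def("depth", "m", 0.5)
  dt <- ncdf4::ncdim_def("time", "days", 1:2)
  vu <- ncdf4::ncvar_def("u", "m s-1", list(dl, dp, dz, dt), prec = "double")
  nc <- ncdf4::nc_create(path, list(vu))
  ncdf4::ncvar_put(nc, vu, array(0, c(5, 4, 1, 2)))
  ncdf4::nc_close(nc)
  expect_error(read_velocity_field(path), "'v' missing")
})

test_that("a synthetic file has the declared dimensions on read", {
  g <- grid_spec(seq(0.05, 2.95, by = 0.1), seq(30.05, 31.95, by = 0.1),
                 depth = c(0.5, 20))
  stopifnot(length(g$lon) == 30, length(g$lat) == 20)
  f <- uniform_field(g, 4, u = 0.1)
  path <- withr::local_tempfile(fileext = ".nc")
  write_velocity_field(f, g, path)
  back <- read_velocity_field(path)
  expect_length(back$field$times, 4)
  expect_equal(dim(back$field$u), c(30L, 20L, 2L, 4L))
})

test_that("field generation and superposition warn/fail sensibly", {
  expect_warning(synth_domain_config(amplitude = 3), "unrealistic")
  cfg <- synth_domain_config(n_mpas = 0)
  dom <- synth_coast_and_mpas(cfg)
  f1 <- synth_flow(cfg, 2, dom$grid)
  f2 <- synth_flow(cfg, 3, dom$grid)
  expect_error(add_fields(f1, f2), "shape")
  fsum <- add_fields(f1, f1)
  expect_equal(fsum$u, 2 * f1$u)
})
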