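test_that("time-step bound is the cell-size / max-speed ratio", {
  expect_equal(choose_time_step(6000, 0.5), 12000)
  expect_equal(choose_time_step(8000, 0.5), 16000)
  expect_equal(choose_time_step(1, 1), 1)
  expect_error(choose_time_step(0, 1), "> 0")
})

test_that("horizontal diffusivity follows the Monin-Ozmidov scaling", {
  expect_equal(horizontal_diffusivity(1e-9, 1000), 10)
  expect_equal(horizontal_diffusivity(1e-9, 7000),
               (1e-9)^(1 / 3) * 7000^(4 / 3), tolerance = 1e-12)
  expect_equal(horizontal_diffusivity(1e-9, 7000), 133.905, tolerance = 1e-4)
  expect_error(horizontal_diffusivity(0, 1000), "> 0")
})

test_that("random-walk components are bounded and have variance 2*Kh/(3*dt)", {
  expect_equal(random_walk_velocity(0, 7200, 5),
               matrix(0, 5, 2, dimnames = list(NULL, c("u_r", "v_r"))))
  set.seed(42)
  draws <- random_walk_velocity(10, 7200, 1e4)
  bound <- sqrt(2 * 10 / 7200)
  expect_equal(bound, 0.0527, tolerance = 1e-3)
  expect_true(all(abs(draws) <= bound))
  set.seed(43)
  big <- random_walk_velocity(10, 7200, 1e5)
  expect_equal(var(big[, 1]), (1 / 3) * 2 * 10 / 7200, tolerance = 0.05)
  expect_equal(var(big[, 2]), (1 / 3) * 2 * 10 / 7200, tolerance = 0.05)
})

test_that("trilinear interpolation is exact for constants, nodes and midpoints", {
  g <- grid_spec(seq(0.5, 9.5), seq(0.5, 4.5), depth = c(1, 10))
  f <- uniform_field(g, 1, u = 0.2, v = 0)
  vel <- interpolate_velocity(f, g, c(3.3, 7.9), c(2.2, 4.0), c(2, 5), 0)
  expect_equal(vel$u, c(0.2, 0.2))
  expect_equal(vel$v, c(0, 0))
  expect_equal(vel$w, c(0, 0))
  # node identity and 1-D midpoint with a gradient in lon
  u <- array(0, c(10, 5, 2, 1)); u[6, 3, 1, 1] <- 0.4
  fg <- velocity_field(1, u, array(0, dim(u)), NULL, g)
  expect_equal(interpolate_velocity(fg, g, 5.5, 2.5, 1, 0)$u, 0.4)
  expect_equal(interpolate_velocity(fg, g, 5.0, 2.5, 1, 0)$u, 0.2)
  expect_equal(interpolate_velocity(fg, g, 5.25, 2.5, 1, 0)$u, 0.3)
})

test_that("the Euler step reproduces the closed-form displacement", {
  # 0.1 m/s east for 7200 s = 720 m; at the equator that is 720/111194.93 deg
  nxt <- advect_step(lon = 0, lat = 0, depth = 0.2,
                     u = 0.1, v = 0, w = 0, dt_s = 7200)
  expect_equal(nxt$lon, 720 / 111194.9266, tolerance = 1e-9)
  expect_equal(nxt$lon, 0.006475, tolerance = 1e-4)
  expect_equal(nxt$lat, 0)
  same <- advect_step(2, 40, 5, 0, 0, 0, dt_s = 7200)
  expect_equal(same, list(lon = 2, lat = 40, depth = 5))
  expect_error(advect_step(0, 89.9, 0, 1, 0, 0, dt_s = 1), "poleward")
})

test_that("boundary rules: loss outside, surface reflection, coastal standstill", {
  fix <- coastal_fixture()
  g <- fix$grid
  bc <- apply_boundaries(g, lon0 = 4.9, lat0 = 40.5,
                         lon1 = 5.2, lat1 = 40.5, depth1 = 1)
  expect_true(bc$lost)
  bc <- apply_boundaries(g, 2, 40.5, 2, 40.5, -0.05)
  expect_equal(bc$depth, 0.05)
  expect_false(bc$lost)
  # aim at the southern land band: position reverted, flagged standstill
  coast_lat <- g$lat[3] + mean(diff(g$lat)) / 2
  bc <- apply_boundaries(g, 2, coast_lat + 0.02, 2, coast_lat - 0.02, 1)
  expect_true(bc$standstill)
  expect_equal(bc$lat, coast_lat + 0.02)
  expect_equal(bc$lon, 2)
})

test_that("diel vertical migration forces the configured depths", {
  cfg <- sim_config(vertical_migration = TRUE)
  # crossing 20:00 -> night depth 0.2 m
  expect_equal(vertical_migration_step(c(50, 50), 18, 20, cfg), c(0.2, 0.2))
  # crossing 08:00 -> day depth 50 m, capped on shallow columns
  expect_equal(vertical_migration_step(c(0.2, 0.2), 6, 8, cfg,
                                       depth_cap = c(Inf, 30)), c(50, 30))
  # no trigger crossed -> unchanged
  expect_equal(vertical_migration_step(c(7, 8), 10, 12, cfg), c(7, 8))
  off <- sim_config(vertical_migration = FALSE)
  expect_equal(vertical_migration_step(5, 18, 20, off), 5)
})

test_that("the seafloor cap is the deepest layer midpoint above the bathymetry", {
  fix <- coastal_fixture()
  g <- fix$grid           # depth levels 0.5, 10, 30, 50, 100, 300
  deep <- which(g$bathymetry > 400 & !g$land_mask, arr.ind = TRUE)[1, ]
  shallow <- which(g$bathymetry > 50 & g$bathymetry < 100 &
                   !g$land_mask, arr.ind = TRUE)[1, ]
  expect_equal(seafloor_depth_cap(g, g$lon[deep[1]], g$lat[deep[2]]), 300)
  expect_equal(seafloor_depth_cap(g, g$lon[shallow[1]], g$lat[shallow[2]]), 50)
})

test_that("release cohorts have the spawning design sizes, depths and positions", {
  fix <- coastal_fixture(n_mpas = 3)
  cfg <- sim_config(larvae_per_event = 50, seed = 9)
  set.seed(9)
  rel <- release_cohort(fix$mpas, fix$grid, cfg)
  expect_equal(nrow(rel), 3 * 10 * 50)
  expect_true(all(rel$depth == 0.2))
  expect_equal(unique(rel$release_day), seq(1, 28, by = 3))
  expect_equal(unname(table(rel$source)), rep(500L, 3), ignore_attr = TRUE)
  # every release point is inside its MPA polygon and at sea
  for (m in fix$mpas) {
    pts <- rel[rel$source == m$id, ]
    expect_true(all(sp::point.in.polygon(pts$lon, pts$lat,
                                         m$ring[, 1], m$ring[, 2]) > 0))
  }
  # an MPA entirely on land is refused by name
  land_mpa <- mpa_site(4L, "ashore", cbind(c(1, 1.1, 1.1, 1, 1),
                                           c(39.0, 39.0, 39.05, 39.05, 39.0)))
  expect_error(release_cohort(c(fix$mpas, list(land_mpa)), fix$grid, cfg),
               "ashore")
})

test_that("stationary flow keeps every larva at its release point", {
  fix <- coastal_fixture(amplitude = 0)
  f <- uniform_field(fix$grid, 60, u = 0, v = 0)
  cfg <- sim_config(pld_days = 20, kh = 0, larvae_per_event = 5, seed = 2)
  tr <- run_simulation(f, fix$grid, fix$mpas, cfg)
  expect_equal(tr$final$lon, tr$particles$lon)
  expect_equal(tr$final$lat, tr$particles$lat)
  expect_true(all(tr$final$status == "active"))
})

test_that("simulations are bit-identical under the same seed", {
  fix <- coastal_fixture()
  f <- uniform_field(fix$grid, 50, u = 0.05)
  cfg <- sim_config(pld_days = 20, larvae_per_event = 5, seed = 77)
  t1 <- run_simulation(f, fix$grid, fix$mpas, cfg)
  t2 <- run_simulation(f, fix$grid, fix$mpas, cfg)
  expect_identical(t1$final, t2$final)
  cfg2 <- cfg; cfg2$seed <- 78L
  t3 <- run_simulation(f, fix$grid, fix$mpas, cfg2)
  expect_false(identical(t1$final, t3$final))
})

test_that("uniform drift matches speed * PLD for PLD 20, 30 and 40 days", {
  fix <- open_ocean_fixture(lon_range = c(0, 14))
  f <- uniform_field(fix$grid, 70, u = 0.1)
  for (pld in c(20, 30, 40)) {
    cfg <- sim_config(pld_days = pld, kh = 0, larvae_per_event = 3, seed = 4)
    tr <- run_simulation(f, fix$grid, fix$mpas, cfg)
    d <- dispersal_distances(tr)
    expected <- 0.1 * pld * 86400 / 1000
    expect_lt(abs(d$pooled[["median"]] - expected) / expected, 0.005)
  }
})

test_that("daily records are spaced a day apart and end at the PLD", {
  fix <- coastal_fixture()
  f <- uniform_field(fix$grid, 50, u = 0.02)
  cfg <- sim_config(pld_days = 5, larvae_per_event = 2, n_events = 2, seed = 3)
  tr <- run_simulation(f, fix$grid, fix$mpas, cfg, record = "daily")
  steps <- sort(unique(tr$daily$step))
  expect_equal(diff(steps), rep(12, length(steps) - 1))
  last_needed <- (cfg$spawn_start_day - 1 + 3 + 5) * 12
  expect_gte(max(steps), last_needed)
})

test_that("a field shorter than the spawning window plus PLD is refused", {
  fix <- coastal_fixture()
  f <- uniform_field(fix$grid, 30, u = 0)
  cfg <- sim_config(pld_days = 30, larvae_per_event = 1)
  expect_error(run_simulation(f, fix$grid, fix$mpas, cfg), "cover")
})

test_that("vertical migration shortens dispersal in a sheared current", {
  cfg <- synth_domain_config(flow = "uniform", amplitude = 0.2,
                             depth_decay_m = 20, coast_edge = "none",
                             n_mpas = 1, lon_range = c(0, 14))
  dom <- synth_coast_and_mpas(cfg)
  f <- synth_flow(cfg, 60, dom$grid)
  base <- sim_config(pld_days = 20, larvae_per_event = 20, seed = 6)
  vm <- base; vm$vertical_migration <- TRUE
  d_pass <- dispersal_distances(run_simulation(f, dom$grid, dom$mpas, base))
  d_vm <- dispersal_distances(run_simulation(f, dom$grid, dom$mpas, vm))
  expect_lt(d_vm$pooled[["median"]], d_pass$pooled[["median"]])
})
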