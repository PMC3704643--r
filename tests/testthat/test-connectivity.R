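test_that("settlement scoring counts final positions inside MPA polygons", {
  fix <- coastal_fixture(n_mpas = 3)
  ctr <- t(vapply(fix$mpas, function(m) colMeans(m$ring[1:4, ]), numeric(2)))
  # larvae from MPA 1: one at its own centroid, one at MPA 3's centroid,
  # one at large, one lost
  tr <- fake_traj(lon0 = rep(ctr[1, 1], 4), lat0 = rep(ctr[1, 2], 4),
                  lon1 = c(ctr[1, 1], ctr[3, 1], 2.5, 99),
                  lat1 = c(ctr[1, 2], ctr[3, 2], 40.9, 99),
                  source = rep(1L, 4),
                  status = c("active", "active", "active", "lost"))
  st <- assign_settlement(tr, fix$mpas)
  expect_equal(st$counts[1, 1], 1L)
  expect_equal(st$counts[3, 1], 1L)
  expect_equal(sum(st$counts), 2L)
  expect_equal(st$released, c(4L, 0L, 0L))
  # all lost -> zero matrix
  tr_lost <- fake_traj(ctr[1, 1], ctr[1, 2], 99, 99, 1L, "lost")
  expect_equal(sum(assign_settlement(tr_lost, fix$mpas)$counts), 0L)
})

test_that("stationary larvae all settle back home (pure local retention)", {
  fix <- coastal_fixture(amplitude = 0)
  f <- uniform_field(fix$grid, 60, u = 0)
  cfg <- sim_config(pld_days = 20, kh = 0, larvae_per_event = 20, seed = 8)
  tr <- run_simulation(f, fix$grid, fix$mpas, cfg)
  st <- assign_settlement(tr, fix$mpas)
  expect_equal(diag(st$counts), rep(200L, 3), ignore_attr = TRUE)
  expect_equal(sum(st$counts) , 600L)
  cm <- connectivity_matrix(st$counts, st$released)
  rs <- recruitment_stats(cm)
  expect_equal(rs$lr, rep(1, 3), ignore_attr = TRUE)
  expect_equal(rs$sr, rep(1, 3), ignore_attr = TRUE)
})

test_that("connection probabilities are counts over released with a floor", {
  counts <- matrix(0L, 3, 3)
  counts[2, 1] <- 50000L
  cm <- connectivity_matrix(counts, released = 50000)
  expect_equal(cm$c[2, 1], 1)
  expect_equal(cm$detection_floor, 0.00002)
  expect_error(connectivity_matrix(counts, c(50000, 0, 50000)), "> 0")
  expect_error(connectivity_matrix(matrix(2, 2, 2), released = 1), "exceed")
  # fuzz: random counts within released always give column sums <= 1
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    rel <- sample(50:500, n)
    cnt <- sapply(rel, function(r) stats::rmultinom(1, sample(0:r, 1),
                                                    rep(1, n + 1))[seq_len(n)])
    cm <- connectivity_matrix(cnt, rel)
    expect_true(all(colSums(cm$c) <= 1 + 1e-12))
    expect_true(all(cm$c >= 0 & cm$c <= 1))
  }
})

test_that("connectance counts nonzero entries over the squared size", {
  expect_equal(connectance(matrix(0, 4, 4)), 0)
  expect_equal(connectance(matrix(1, 4, 4)), 1)
  m <- matrix(0, 115, 115)
  m[1, 2] <- 0.5
  expect_equal(connectance(m), 1 / 13225)
  d <- diag(0.1, 5)                    # self-loops count
  expect_equal(connectance(d), 5 / 25)
})

test_that("self-recruitment splits local from subsidised recruitment", {
  m <- matrix(0, 3, 3)
  m[1, 1] <- 0.2                       # pure self-recruiter
  m[2, 1] <- 0.2                       # node 2: only incoming, no retention
  m[3, 3] <- 0.2; m[3, 2] <- 0.2       # node 3: half and half
  rs <- recruitment_stats(m)
  expect_equal(rs$sr, c(1, 0, 0.5))
  expect_equal(rs$subsidy, c(0, 1, 0.5))
  expect_equal(rs$lr, c(0.2, 0, 0.2))
  # an MPA with no recruits at all has undefined (NA) self-recruitment
  m2 <- matrix(0, 2, 2); m2[1, 1] <- 0.1
  expect_true(is.na(recruitment_stats(m2)$sr[2]))
  # identity sr + subsidy = 1 wherever defined
  set.seed(12)
  mm <- matrix(runif(16, 0, 0.1), 4, 4)
  rs <- recruitment_stats(mm)
  expect_equal(rs$sr + rs$subsidy, rep(1, 4))
})

test_that("dispersal distance is the haversine release-to-final distance", {
  tr <- fake_traj(lon0 = c(0, 0), lat0 = c(0, 0),
                  lon1 = c(0, 1), lat1 = c(0, 0), source = c(1L, 1L))
  d <- dispersal_distances(tr)
  expect_equal(unname(d$per_larva[1]), 0)
  expect_equal(unname(d$per_larva[2]), 111.19, tolerance = 1e-4)
  expect_equal(d$per_mpa$mean_km, mean(d$per_larva))
  expect_equal(great_circle_km(0, 0, 1, 0), 2 * pi * 6371 / 360,
               tolerance = 1e-9)
})

test_that("pairwise MPA distances and nearest neighbors are measured on the sphere", {
  mk <- function(id, lon) {
    mpa_site(id, paste0("m", id),
             cbind(lon + c(0, 0.1, 0.1, 0, 0), c(0, 0, 0.1, 0.1, 0)))
  }
  km_per_deg <- 2 * pi * 6371 / 360
  # three collinear MPAs at 0, 100 and 300 km along the equator
  mpas <- list(mk(1L, 0), mk(2L, 100 / km_per_deg), mk(3L, 300 / km_per_deg))
  pd <- mpa_pairwise_distances(mpas)
  expect_equal(unname(pd$nearest_neighbor_km), c(100, 100, 200),
               tolerance = 1e-6)
  expect_equal(pd$pairwise[1, 3], 300, tolerance = 1e-6)
  expect_warning(mpa_pairwise_distances(list(mk(1L, 0), mk(2L, 0))),
                 "degenerate")
  expect_error(mpa_pairwise_distances(mpas[1]), "at least 2")
})

test_that("per-source accounting closes exactly", {
  fix <- coastal_fixture(n_mpas = 3, flow = "boundary_jet", amplitude = 0.3)
  f <- synth_flow(fix$cfg, 60, fix$grid)
  cfg <- sim_config(pld_days = 15, larvae_per_event = 10, seed = 21)
  tr <- run_simulation(f, fix$grid, fix$mpas, cfg)
  st <- assign_settlement(tr, fix$mpas)
  cm <- connectivity_matrix(st$counts, st$released)
  lost_by_src <- tapply(tr$final$status == "lost", tr$final$source, sum)
  at_large <- st$released - colSums(st$counts) - as.integer(lost_by_src)
  expect_true(all(at_large >= 0))
  # settled + at-large + lost = released, per source
  expect_equal(colSums(st$counts) + at_large + as.integer(lost_by_src),
               st$released, ignore_attr = TRUE)
})

test_that("a connectivity matrix survives the CSV round trip", {
  counts <- matrix(c(5L, 0L, 2L, 1L, 3L, 0L, 0L, 0L, 4L), 3, 3)
  cm <- connectivity_matrix(counts, released = c(10, 10, 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_connectivity_csv(cm, path)
  back <- read_connectivity_csv(path, released = 10)
  expect_equal(back$c, cm$c, ignore_attr = TRUE)
})

test_that("trajectory tables and recruitment summaries export to disk", {
  fix <- coastal_fixture(amplitude = 0)
  f <- uniform_field(fix$grid, 50, u = 0.02)
  cfg <- sim_config(pld_days = 4, larvae_per_event = 2, n_events = 2, seed = 31)
  tr <- run_simulation(f, fix$grid, fix$mpas, cfg, record = "daily")
  tp <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, tp)
  tab <- utils::read.csv(tp)
  expect_setequal(names(tab), c("particle_id", "source_mpa", "time_s",
                                "lon", "lat", "depth", "status"))
  expect_equal(sort(unique(diff(sort(unique(tab$time_s))))), 86400)
  # final-only export has one row per particle at its PLD end
  tr2 <- run_simulation(f, fix$grid, fix$mpas, cfg)
  write_trajectory_csv(tr2, tp)
  tab2 <- utils::read.csv(tp)
  expect_equal(nrow(tab2), tr2$released)
  expect_equal(unique(tab2$time_s - (tab2$particle_id * 0)) %in%
               ((cfg$pld_days + c(0, 3)) * 86400), c(TRUE, TRUE))

  st <- assign_settlement(tr2, fix$mpas)
  cm <- connectivity_matrix(st$counts, st$released)
  jp <- withr::local_tempfile(fileext = ".json")
  write_recruitment_json(cm, jp)
  js <- jsonlite::read_json(jp)
  expect_equal(js$connectance, connectance(cm))
  expect_length(js$per_mpa, 3)
  ex <- export_summary(tr2, fix$grid, fix$mpas)
  cp <- withr::local_tempfile(fileext = ".csv")
  write_export_csv(ex, cp, scenario = "demo")
  expect_equal(utils::read.csv(cp)$frac_on_shelf, ex$frac_on_shelf)
})
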