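#' Admissible advection time step
#'
#' Upper bound on the iteration time step: the ratio of horizontal cell size
#' to maximum current speed, so a particle cannot cross more than one cell
#' boundary per step. At basin-model scales (6-8 km cells, ~0.5 m/s peak
#' currents) the bound is 12000-16000 s; the default configuration uses a
#' comfortably smaller 7200 s (2 h) step.
#'
#' @param cell_length_m horizontal cell width in meters.
#' @param max_speed_mps maximum current speed in m/s.
#' @return the bound in seconds; configured steps must not exceed it.
#' @export
choose_time_step <- function(cell_length_m, max_speed_mps) {
  if (cell_length_m <= 0 || max_speed_mps <= 0) {
    stop_domain("cell length and max speed must be > 0")
  }
  cell_length_m / max_speed_mps
}

#' Lagrangian horizontal diffusion coefficient (Monin-Ozmidov scaling)
#'
#' \code{K_h = epsilon^(1/3) * l^(4/3)}, with \code{epsilon} the turbulent
#' dissipation rate (m^2 s^-3; 1e-9 is the classical open-ocean value) and
#' \code{l} the grid-cell length. This sets the amplitude of the sub-grid
#' random walk that stands in for unresolved coastal eddies.
#'
#' @param epsilon turbulent dissipation rate (m^2 s^-3).
#' @param cell_length_m grid-cell length l (m).
#' @return K_h in m^2/s.
#' @export
#' @examples
#' horizontal_diffusivity(1e-9, 1000)  # 10 m^2/s
horizontal_diffusivity <- function(epsilon, cell_length_m) {
  if (epsilon <= 0 || cell_length_m <= 0) {
    stop_domain("epsilon and cell length must be > 0")
  }
  epsilon^(1 / 3) * cell_length_m^(4 / 3)
}

#' Random-walk velocity components
#'
#' Each horizontal component is an independent draw
#' \code{delta * sqrt(2 K_h / dt)} with \code{delta ~ U[-1, 1]}, added to the
#' interpolated current before the Euler step. Per component the variance is
#' \code{(1/3) * 2 K_h / dt}, which makes the 2-D mean squared displacement
#' grow as \code{(4/3) K_h t}.
#'
#' @param kh horizontal diffusivity (m^2/s), >= 0.
#' @param dt_s time step (s).
#' @param n number of particles.
#' @return an \code{n x 2} matrix of (u_r, v_r) in m/s.
#' @export
random_walk_velocity <- function(kh, dt_s, n = 1L) {
  if (kh < 0 || dt_s <= 0) stop_domain("need kh >= 0 and dt_s > 0")
  amp <- sqrt(2 * kh / dt_s)
  matrix(stats::runif(2L * n, -1, 1) * amp, ncol = 2L,
         dimnames = list(NULL, c("u_r", "v_r")))
}

#' Trilinear velocity interpolation
#'
#' Interpolates the daily snapshot covering \code{time_s} linearly in lon,
#' lat and depth among the 8 surrounding grid nodes (fields are
#' piecewise-constant in time at daily resolution). Land nodes contribute
#' their stored zero velocity, which damps the flow smoothly toward the
#' coast. Queries outside the axis range use constant extrapolation of the
#' nearest face (the boundary handler decides what happens to such
#' particles).
#'
#' @param field a \code{\link{velocity_field}}.
#' @param grid its \code{\link{grid_spec}}.
#' @param lon,lat,depth query positions (vectors).
#' @param time_s simulation time in seconds from the start of the field.
#' @return list of vectors \code{u}, \code{v}, \code{w} (m/s).
#' @export
interpolate_velocity <- function(field, grid, lon, lat, depth, time_s) {
  nt <- dim(field$u)[4]
  day <- min(max(floor(time_s / 86400) + 1L, 1L), nt)
  nlon <- length(grid$lon); nlat <- length(grid$lat); nz <- length(grid$depth)

  bracket <- function(x, ax) {
    n <- length(ax)
    if (n == 1L) return(list(i = rep(1L, length(x)), w = rep(0, length(x))))
    i <- findInterval(x, ax)
    i <- pmin(pmax(i, 1L), n - 1L)
    w <- (x - ax[i]) / (ax[i + 1L] - ax[i])
    list(i = i, w = pmin(pmax(w, 0), 1))
  }
  bx <- bracket(lon, grid$lon)
  by <- bracket(lat, grid$lat)
  bz <- bracket(depth, grid$depth)

  slab <- (day - 1L) * nlon * nlat * nz
  idx <- function(di, dj, dk) {
    i <- pmin(bx$i + di, nlon); j <- pmin(by$i + dj, nlat)
    k <- pmin(bz$i + dk, nz)
    slab + i + (j - 1L) * nlon + (k - 1L) * nlon * nlat
  }
  interp <- function(a) {
    if (is.null(a)) return(rep(0, length(lon)))
    wx <- bx$w; wy <- by$w; wz <- bz$w
    (1 - wz) * ((1 - wy) * ((1 - wx) * a[idx(0L, 0L, 0L)] +
                            wx * a[idx(1L, 0L, 0L)]) +
                wy * ((1 - wx) * a[idx(0L, 1L, 0L)] +
                      wx * a[idx(1L, 1L, 0L)])) +
    wz * ((1 - wy) * ((1 - wx) * a[idx(0L, 0L, 1L)] +
                      wx * a[idx(1L, 0L, 1L)]) +
          wy * ((1 - wx) * a[idx(0L, 1L, 1L)] +
                wx * a[idx(1L, 1L, 1L)]))
  }
  list(u = interp(field$u), v = interp(field$v), w = interp(field$w))
}

#' One explicit Euler advection step
#'
#' Forward-Euler position update on the sphere: angular increments are the
#' metric conversion of (current + random-walk) velocity,
#' \code{dlat = v dt / R}, \code{dlon = u dt / (R cos lat)} (in degrees, with
#' R = 6371 km). The random-walk components apply to the horizontal only;
#' depth changes by \code{w dt}.
#'
#' @param lon,lat,depth current positions (vectors, degrees / m).
#' @param u,v,w velocities (m/s), as from \code{\link{interpolate_velocity}}.
#' @param ur,vr random-walk components (m/s), default 0.
#' @param dt_s time step (s).
#' @return list of updated \code{lon}, \code{lat}, \code{depth}.
#' @export
advect_step <- function(lon, lat, depth, u, v, w = 0, ur = 0, vr = 0, dt_s) {
  coslat <- cos(lat * pi / 180)
  if (any(coslat <= 0.01)) {
    stop_domain("advection undefined poleward of +-89.4 degrees")
  }
  list(lon = lon + (u + ur) * dt_s / (M_PER_DEG * coslat),
       lat = lat + (v + vr) * dt_s / M_PER_DEG,
       depth = depth + w * dt_s)
}

#' Boundary rules for candidate positions
#'
#' Applies, in order: loss at the outer domain limits (particle removed from
#' all further accounting), reflection of negative depths back into the water
#' column, a clamp to the deepest layer midpoint, and the coastal standstill
#' rule -- a particle whose candidate cell is land is retained in place: this
#' step's move is cancelled and it stays at its last sea position, free to
#' move again at the next iteration (and scoreable at settlement if still
#' there at the end of its PLD).
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param lon0,lat0 pre-step (last sea) positions.
#' @param lon1,lat1,depth1 candidate post-advection positions.
#' @return list \code{lon}, \code{lat}, \code{depth}, \code{lost} (logical),
#'   \code{standstill} (logical).
#' @export
apply_boundaries <- function(grid, lon0, lat0, lon1, lat1, depth1) {
  lost <- lon1 < grid$lon_edges[1] | lon1 > grid$lon_edges[length(grid$lon_edges)] |
          lat1 < grid$lat_edges[1] | lat1 > grid$lat_edges[length(grid$lat_edges)]
  depth1 <- ifelse(depth1 < 0, -depth1, depth1)      # sent back into water
  depth1 <- pmin(depth1, max(grid$depth))            # never below bottom layer
  standstill <- rep(FALSE, length(lon1))
  chk <- which(!lost)
  if (length(chk)) {
    onland <- is_land_at(grid, lon1[chk], lat1[chk])
    ss <- chk[onland]
    standstill[ss] <- TRUE
    lon1[ss] <- lon0[ss]; lat1[ss] <- lat0[ss]
  }
  list(lon = lon1, lat = lat1, depth = depth1,
       lost = lost, standstill = standstill)
}

#' Diel vertical migration trigger
#'
#' When the simulation clock crosses the ascent hour the larva is placed at
#' the night depth (20 cm); when it crosses the descent hour it is placed at
#' the day depth (50 m), capped at the deepest layer midpoint above the local
#' seafloor on shallow columns. Between triggers depth evolves only through
#' \code{w}.
#'
#' @param depth current depths (m).
#' @param hour_prev,hour_cur clock hour at the previous and current iteration
#'   (0-24, local).
#' @param cfg a \code{\link{sim_config}} with \code{vertical_migration = TRUE}.
#' @param depth_cap per-particle maximum admissible depth (m), from
#'   \code{\link{seafloor_depth_cap}}.
#' @return updated depth vector.
#' @export
vertical_migration_step <- function(depth, hour_prev, hour_cur, cfg,
                                    depth_cap = Inf) {
  if (!isTRUE(cfg$vertical_migration)) return(depth)
  crossed <- function(h) {
    if (hour_prev <= hour_cur) hour_prev < h & h <= hour_cur
    else h > hour_prev | h <= hour_cur  # midnight wrap
  }
  if (crossed(cfg$ascend_hour)) depth[] <- cfg$night_depth_m
  if (crossed(cfg$descend_hour)) depth <- pmin(cfg$day_depth_m, depth_cap)
  depth
}

#' Deepest admissible depth over each position
#'
#' The deepest layer midpoint lying above the local seafloor (velocity is
#' defined at layer midpoints and vanishes at the bottom, so larvae never
#' touch the seabed); on columns shallower than the first midpoint, half the
#' local water depth.
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param lon,lat positions.
#' @return vector of depths (m).
#' @export
seafloor_depth_cap <- function(grid, lon, lat) {
  ij <- grid_cell(grid, lon, lat)
  b <- rep(max(grid$depth), length(lon))
  ok <- !is.na(ij$i) & !is.na(ij$j)
  bathy <- grid$bathymetry[cbind(ij$i[ok], ij$j[ok])]
  k <- findInterval(bathy, grid$depth)
  cap <- ifelse(k >= 1L, grid$depth[pmax(k, 1L)], bathy / 2)
  b[ok] <- cap
  pmax(b, 0.2)
}

#' Simulation configuration
#'
#' Bundles the tracker parameters. Defaults follow the dusky-grouper study
#' design: 10 release events every 3 days from the 1st of the spawning month,
#' 1000 larvae per event per MPA released at 20 cm depth, a 7200 s (2 h)
#' iteration step, positions recorded daily, a 30-day pelagic larval
#' duration, and Monin-Ozmidov diffusion with epsilon = 1e-9 m^2 s^-3.
#'
#' @param pld_days pelagic larval duration in days (study range 20-40).
#' @param dt_s iteration time step (s); must divide 86400 and respect
#'   \code{\link{choose_time_step}}.
#' @param record_interval_s recording cadence (default 86400 s = every 12
#'   iterations at the default step).
#' @param epsilon turbulent dissipation rate (m^2 s^-3).
#' @param kh horizontal diffusivity (m^2/s); derived from \code{epsilon} and
#'   the grid-cell length when \code{NULL}. Set 0 to disable the random walk.
#' @param release_depth_m release depth (m); eggs ascend immediately after
#'   spawning, hence 0.2 m.
#' @param vertical_migration logical; diel migration scenario.
#' @param night_depth_m,day_depth_m,ascend_hour,descend_hour diel migration
#'   parameters (ascend to 0.2 m at 20 h, descend to 50 m at 8 h).
#' @param spawn_start_day first release day (index into the field's days).
#' @param n_events number of release events.
#' @param event_interval_days days between releases.
#' @param larvae_per_event larvae per MPA per event.
#' @param seed RNG seed; the full simulation is deterministic given the seed.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(pld_days = 30, dt_s = 7200, record_interval_s = 86400,
                       epsilon = 1e-9, kh = NULL, release_depth_m = 0.2,
                       vertical_migration = FALSE, night_depth_m = 0.2,
                       day_depth_m = 50, ascend_hour = 20, descend_hour = 8,
                       spawn_start_day = 1, n_events = 10,
                       event_interval_days = 3, larvae_per_event = 1000,
                       seed = 1L) {
  if (pld_days <= 0) stop_domain("pld_days must be positive")
  if (86400 %% dt_s != 0) stop_domain("dt_s must divide 86400")
  if (record_interval_s %% dt_s != 0) {
    stop_domain("record_interval_s must be a multiple of dt_s")
  }
  structure(list(
    pld_days = pld_days, dt_s = dt_s, record_interval_s = record_interval_s,
    epsilon = epsilon, kh = kh, release_depth_m = release_depth_m,
    vertical_migration = vertical_migration, night_depth_m = night_depth_m,
    day_depth_m = day_depth_m, ascend_hour = ascend_hour,
    descend_hour = descend_hour, spawn_start_day = spawn_start_day,
    n_events = n_events, event_interval_days = event_interval_days,
    larvae_per_event = larvae_per_event, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Release a spawning cohort
#'
#' For each MPA and each release event, places \code{larvae_per_event}
#' particles at uniform-random sea points inside the MPA polygon at the
#' configured release depth. Events fall every \code{event_interval_days}
#' from \code{spawn_start_day} (days 1, 4, ..., 28 of the spawning month
#' under the defaults).
#'
#' @param mpas list of \code{\link{mpa_site}}.
#' @param grid a \code{\link{grid_spec}}.
#' @param cfg a \code{\link{sim_config}}.
#' @return data.frame with columns \code{id}, \code{source}, \code{event},
#'   \code{release_day}, \code{lon}, \code{lat}, \code{depth}.
#' @export
release_cohort <- function(mpas, grid, cfg) {
  per_mpa <- cfg$n_events * cfg$larvae_per_event
  if (length(mpas) == 0) {
    return(data.frame(id = integer(), source = integer(), event = integer(),
                      release_day = integer(), lon = numeric(),
                      lat = numeric(), depth = numeric()))
  }
  out <- vector("list", length(mpas))
  for (m in seq_along(mpas)) {
    mpa <- mpas[[m]]
    bb <- apply(mpa$ring, 2, range)
    pts <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(pts) < per_mpa) {
      need <- per_mpa - nrow(pts)
      cand <- cbind(stats::runif(4L * need, bb[1, 1], bb[2, 1]),
                    stats::runif(4L * need, bb[1, 2], bb[2, 2]))
      inside <- sp::point.in.polygon(cand[, 1], cand[, 2],
                                     mpa$ring[, 1], mpa$ring[, 2]) > 0
      sea <- inside & !is_land_at(grid, cand[, 1], cand[, 2])
      pts <- rbind(pts, cand[sea, , drop = FALSE])
      tries <- tries + 1L
      if (tries > 200L && nrow(pts) == 0L) {
        stop_domain("MPA '", mpa$name, "' has no overlap with sea cells")
      }
    }
    pts <- pts[seq_len(per_mpa), , drop = FALSE]
    ev <- rep(seq_len(cfg$n_events), each = cfg$larvae_per_event)
    out[[m]] <- data.frame(
      source = mpa$id, event = ev,
      release_day = cfg$spawn_start_day + (ev - 1L) * cfg$event_interval_days,
      lon = pts[, 1], lat = pts[, 2], depth = cfg$release_depth_m)
  }
  res <- do.call(rbind, out)
  res <- cbind(id = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Run the Lagrangian dispersal simulation
#'
#' Integrates every released larva for exactly \code{pld_days} with the 2 h
#' Euler/random-walk scheme, applying the boundary rules (loss at open
#' boundaries, surface reflection, coastal standstill -- a cancelled step, not
#' a permanent freeze) and, optionally, diel vertical migration. Deterministic given \code{cfg$seed}. Returns the final
#' position of every particle at the end of its PLD -- settlement is scored
#' from these final positions only, with no competency window.
#'
#' @param field a \code{\link{velocity_field}} covering the spawning window
#'   plus the PLD.
#' @param grid its \code{\link{grid_spec}}.
#' @param mpas list of \code{\link{mpa_site}} (release polygons).
#' @param cfg a \code{\link{sim_config}}.
#' @param record \code{"final"} (default) or \code{"daily"} to also keep the
#'   per-day position history (memory grows with particles x days).
#' @return an object of class \code{trajectory_record}: a list with
#'   \code{particles} (release table), \code{final} (final lon/lat/depth and
#'   status per particle), \code{released}/\code{lost}/\code{standstill}
#'   counts, optional \code{daily} history, and the \code{cfg} used.
#' @export
run_simulation <- function(field, grid, mpas, cfg, record = c("final", "daily")) {
  record <- match.arg(record)
  set.seed(cfg$seed)
  dt <- cfg$dt_s
  spd <- 86400L %/% dt                      # steps per day
  pld_steps <- cfg$pld_days * spd
  ndays_needed <- cfg$spawn_start_day - 1 +
    (cfg$n_events - 1) * cfg$event_interval_days + cfg$pld_days
  if (dim(field$u)[4] < ndays_needed) {
    stop_domain("field covers ", dim(field$u)[4], " days but ",
                ndays_needed, " are needed (spawning window + PLD)")
  }
  kh <- if (is.null(cfg$kh)) {
    horizontal_diffusivity(cfg$epsilon, grid$cell_length_m)
  } else cfg$kh

  rel <- release_cohort(mpas, grid, cfg)
  n <- nrow(rel)
  lon <- rel$lon; lat <- rel$lat; depth <- rel$depth
  rel_step <- (rel$release_day - 1L) * spd
  end_step <- rel_step + pld_steps
  status <- rep(0L, n)                      # 0 active, 1 lost, 2 standstill
  total_steps <- if (n > 0) max(end_step) else 0L

  daily <- if (record == "daily") vector("list", total_steps %/% spd + 1L)
           else NULL
  rec_every <- cfg$record_interval_s %/% dt

  for (s in seq_len(total_steps) - 1L) {
    if (!is.null(daily) && s %% rec_every == 0L) {
      daily[[s %/% rec_every + 1L]] <- data.frame(
        step = s, id = rel$id, lon = lon, lat = lat, depth = depth,
        status = status)
    }
    born <- rel_step <= s & s < end_step
    act <- which(born & status != 1L)   # standstill is transient, not loss
    if (length(act)) {
      t_now <- s * dt
      if (isTRUE(cfg$vertical_migration)) {
        hour_cur <- (t_now / 3600) %% 24
        hour_prev <- ((t_now - dt) / 3600) %% 24
        cap <- seafloor_depth_cap(grid, lon[act], lat[act])
        newly <- rel_step[act] == s    # first step: no crossing yet
        d2 <- vertical_migration_step(depth[act], hour_prev, hour_cur, cfg, cap)
        depth[act[!newly]] <- d2[!newly]
      }
      vel <- interpolate_velocity(field, grid, lon[act], lat[act],
                                  depth[act], t_now)
      rw <- if (kh > 0) random_walk_velocity(kh, dt, length(act))
            else matrix(0, length(act), 2)
      nxt <- advect_step(lon[act], lat[act], depth[act],
                         vel$u, vel$v, vel$w, rw[, 1], rw[, 2], dt)
      bc <- apply_boundaries(grid, lon[act], lat[act],
                             nxt$lon, nxt$lat, nxt$depth)
      lon[act] <- bc$lon; lat[act] <- bc$lat; depth[act] <- bc$depth
      status[act] <- 0L
      status[act[bc$lost]] <- 1L
      status[act[bc$standstill]] <- 2L
    }
    stopifnot(sum(status == 0L) + sum(status == 1L) + sum(status == 2L) == n)
  }
  if (!is.null(daily)) {
    daily[[total_steps %/% rec_every + 1L]] <- data.frame(
      step = total_steps, id = rel$id, lon = lon, lat = lat, depth = depth,
      status = status)
  }

  structure(list(
    particles = rel,
    final = data.frame(id = rel$id, source = rel$source,
                       lon = lon, lat = lat, depth = depth,
                       status = c("active", "lost", "standstill")[status + 1L]),
    released = n, lost = sum(status == 1L), standstill = sum(status == 2L),
    daily = if (is.null(daily)) NULL else do.call(rbind, daily),
    kh = kh, cfg = cfg
  ), class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf(
    "trajectory_record: %d larvae (%d lost, %d standstill), PLD %g d, K_h %.2f m2/s\n",
    x$released, x$lost, x$standstill, x$cfg$pld_days, x$kh))
  invisible(x)
}
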