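CONFIG_DEFAULTS <- list(
  domain = list(),            # synth_domain_config() arguments
  simulation = list(),        # sim_config() arguments
  n_days = NULL,              # field length; derived from schedule when NULL
  field_path = NULL,          # read field from NetCDF instead of synthesis
  mpas_path = NULL,           # read MPAs from GeoJSON instead of synthesis
  production = "uniform",
  out_dir = NULL
)

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration with sections \code{domain} (arguments of
#' \code{\link{synth_domain_config}}), \code{simulation} (arguments of
#' \code{\link{sim_config}}) and top-level keys \code{n_days},
#' \code{field_path}, \code{mpas_path}, \code{production}, \code{out_dir}.
#' Missing simulation keys take the study defaults (2 h step, 30 d PLD, 10
#' events every 3 d of 1000 larvae at 0.2 m, epsilon 1e-9). Unknown keys are
#' an error, as is a time step exceeding the admissibility bound of the
#' configured flow.
#'
#' @param path YAML file, or a list with the same structure.
#' @return validated configuration list with \code{domain_cfg} and
#'   \code{sim_cfg} filled in.
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(CONFIG_DEFAULTS))
  if (length(unknown)) {
    stop_domain("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(CONFIG_DEFAULTS, raw)
  bad <- setdiff(names(cfg$domain), names(formals(synth_domain_config)))
  if (length(bad)) {
    stop_domain("unknown domain key(s): ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(names(cfg$simulation), names(formals(sim_config)))
  if (length(bad)) {
    stop_domain("unknown simulation key(s): ", paste(bad, collapse = ", "))
  }
  cfg$domain_cfg <- do.call(synth_domain_config, cfg$domain)
  cfg$sim_cfg <- do.call(sim_config, cfg$simulation)
  if (is.null(cfg$n_days)) {
    sc <- cfg$sim_cfg
    cfg$n_days <- sc$spawn_start_day - 1 +
      (sc$n_events - 1) * sc$event_interval_days + sc$pld_days
  }
  cfg
}

check_dt_admissible <- function(sim_cfg, grid, field) {
  vmax <- max_speed(field)
  if (vmax > 0) {
    bound <- choose_time_step(grid$cell_length_m, vmax)
    if (sim_cfg$dt_s > bound) {
      stop_domain(sprintf(
        "dt = %g s exceeds the admissible bound cell/max_speed = %.0f s",
        sim_cfg$dt_s, bound))
    }
  }
  invisible(TRUE)
}

#' Run the full dispersal-to-report pipeline
#'
#' Executes, in order: domain synthesis (or file input) -> simulation ->
#' settlement and connectivity -> graph metrics -> shelf export, asserting
#' particle conservation at each stage boundary, and returns every artifact
#' together with a run manifest (configuration snapshot, seed, stage
#' timings). When \code{out_dir} is set, the standard-format outputs
#' (velocity NetCDF, MPA GeoJSON, connectivity CSV, node/edge CSVs,
#' abundance NetCDF, manifest JSON) are written there.
#'
#' @param config a file path or list accepted by \code{\link{load_config}}.
#' @return list with \code{grid}, \code{mpas}, \code{field}, \code{traj},
#'   \code{settlement}, \code{cm}, \code{graph}, \code{ranks},
#'   \code{export}, \code{stats}, \code{manifest}.
#' @export
pipeline_run <- function(config) {
  cfg <- load_config(config)
  t0 <- Sys.time()
  timings <- c()
  tick <- function(stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    t0 <<- Sys.time()
  }

  stage <- "synth"
  res <- tryCatch({
    if (!is.null(cfg$mpas_path)) {
      mpas <- read_mpas_geojson(cfg$mpas_path)
      dom <- synth_coast_and_mpas(cfg$domain_cfg)
      grid <- dom$grid
    } else {
      dom <- synth_coast_and_mpas(cfg$domain_cfg)
      grid <- dom$grid; mpas <- dom$mpas
    }
    if (!is.null(cfg$field_path)) {
      rd <- read_velocity_field(cfg$field_path)
      field <- rd$field; grid <- rd$grid
    } else {
      field <- synth_flow(cfg$domain_cfg, cfg$n_days, grid)
    }
    tick("synth")

    stage <- "simulate"
    check_dt_admissible(cfg$sim_cfg, grid, field)
    traj <- run_simulation(field, grid, mpas, cfg$sim_cfg)
    stopifnot(traj$released == nrow(traj$final))
    tick("simulate")

    stage <- "connect"
    if (length(mpas) == 0) stop_domain("no MPAs to connect")
    st <- assign_settlement(traj, mpas)
    stopifnot(sum(st$counts) <= sum(st$released))
    cm <- connectivity_matrix(st$counts, st$released)
    tick("connect")

    stage <- "graph"
    g <- build_graph(cm)
    ranks <- rank_nodes(g)
    tick("graph")

    stage <- "export"
    ex <- export_summary(traj, grid, mpas, cfg$production)
    stopifnot(ex$n_on_shelf + ex$n_open_sea + traj$lost == traj$released)
    tick("export")

    stage <- "stats"
    stats <- list(recruitment = recruitment_stats(cm),
                  distances = mpa_pairwise_distances(mpas),
                  dispersal = dispersal_distances(traj)$pooled)
    tick("stats")

    list(grid = grid, mpas = mpas, field = field, traj = traj,
         settlement = st, cm = cm, graph = g, ranks = ranks,
         export = ex, stats = stats)
  }, error = function(e) {
    stop_domain("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  })

  res$manifest <- list(
    package_version = as.character(utils::packageVersion("mpaconnect")),
    seed = cfg$sim_cfg$seed,
    config = cfg[setdiff(names(cfg), c("domain_cfg", "sim_cfg"))],
    particles = list(released = res$traj$released, lost = res$traj$lost,
                     standstill = res$traj$standstill),
    stage_seconds = as.list(timings),
    finished = format(Sys.time(), tz = "UTC", usetz = TRUE))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(cfg$out_dir, f)
    write_velocity_field(res$field, res$grid, p("field.nc"))
    write_mpas_geojson(res$mpas, p("mpas.geojson"))
    write_connectivity_csv(res$cm, p("connectivity.csv"))
    write_graph_csv(res$graph, p("edges.csv"), p("nodes.csv"))
    abundance_map_write(res$export, res$grid, p("abundance.nc"))
    jsonlite::write_json(res$manifest, p("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
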