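#' Response metrics of one simulation
#'
#' Runs the full post-processing chain on one trajectory record: dispersal
#' distances, connectivity matrix, graph clusters and shelf export, and
#' returns the scalar responses tabulated in the sensitivity analyses.
#'
#' @param traj a \code{\link{trajectory_record}}.
#' @param grid,mpas the domain.
#' @return one-row data.frame: \code{median_disp_km}, \code{p75_disp_km},
#'   \code{connectance}, \code{n_strong}, \code{n_weak},
#'   \code{frac_on_shelf}, \code{frac_shelf_unseeded}.
#' @export
scenario_metrics <- function(traj, grid, mpas) {
  dd <- dispersal_distances(traj)
  st <- assign_settlement(traj, mpas)
  cm <- connectivity_matrix(st$counts, st$released)
  g <- build_graph(cm)
  ex <- export_summary(traj, grid, mpas)
  data.frame(
    median_disp_km = unname(dd$pooled["median"]),
    p75_disp_km = unname(dd$pooled["q75"]),
    connectance = connectance(cm),
    n_strong = strong_clusters(g)$n_clusters,
    n_weak = weak_clusters(g)$n_clusters,
    frac_on_shelf = ex$frac_on_shelf,
    frac_shelf_unseeded = ex$frac_shelf_unseeded)
}

#' Run a plan of simulation scenarios
#'
#' Executes the dispersal pipeline for every cell of a scenario plan and
#' returns a tidy result table, one row per (scenario, replicate). Replicate
#' r of every scenario uses seed \code{base_seed + r}, so contrasts between
#' scenarios are paired through common random numbers.
#'
#' @param field a \code{\link{velocity_field}} long enough for the largest
#'   spawning window + PLD in the plan, or a list of such fields
#'   (independent realizations, e.g. different years): replicate r then uses
#'   field \code{((r - 1) mod length) + 1}, so inter-annual flow variability
#'   enters the replicate spread.
#' @param grid,mpas the domain.
#' @param base_cfg a \code{\link{sim_config}} supplying every parameter not
#'   varied by the plan.
#' @param plan data.frame of scenario axes; recognised columns:
#'   \code{pld} (days), \code{vertical_migration} (logical),
#'   \code{spawn_start_day} (day index of the first release event). Other
#'   columns are carried through to the output unchanged.
#' @param replicates number of replicates per scenario (>= 1).
#' @param base_seed replicate r uses seed \code{base_seed + r}.
#' @return data.frame: plan columns + \code{replicate}, \code{seed}, and the
#'   \code{\link{scenario_metrics}} responses.
#' @export
run_scenarios <- function(field, grid, mpas, base_cfg, plan,
                          replicates = 1L, base_seed = 1000L) {
  if (replicates < 1L) stop_domain("need at least one replicate")
  rows <- vector("list", nrow(plan) * replicates)
  k <- 0L
  for (sc in seq_len(nrow(plan))) {
    cfg <- base_cfg
    if ("pld" %in% names(plan)) cfg$pld_days <- plan$pld[sc]
    if ("vertical_migration" %in% names(plan)) {
      cfg$vertical_migration <- plan$vertical_migration[sc]
    }
    if ("spawn_start_day" %in% names(plan)) {
      cfg$spawn_start_day <- plan$spawn_start_day[sc]
    }
    fields <- if (inherits(field, "velocity_field")) list(field) else field
    for (r in seq_len(replicates)) {
      cfg$seed <- as.integer(base_seed + r)
      fld <- fields[[(r - 1L) %% length(fields) + 1L]]
      traj <- run_simulation(fld, grid, mpas, cfg)
      k <- k + 1L
      rows[[k]] <- cbind(plan[sc, , drop = FALSE],
                         replicate = r, seed = cfg$seed,
                         scenario_metrics(traj, grid, mpas))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear regression of a response on PLD
#'
#' Ordinary least squares of a response variable on pelagic larval duration
#' in days; the slope is the change in the response per one-day increase in
#' PLD. Reports slope, its standard error, adjusted R-squared and the
#' two-sided p-value from the t distribution with n - 2 df.
#'
#' @param table a \code{\link{run_scenarios}} result (or any data.frame with
#'   a \code{pld} column).
#' @param response name of the response column.
#' @return object of class \code{pld_regression}: list with \code{slope},
#'   \code{se}, \code{adj_r_squared}, \code{p_value}, \code{n},
#'   \code{intercept}.
#' @export
pld_regression <- function(table, response) {
  if (!"pld" %in% names(table)) stop_domain("table must have a 'pld' column")
  if (!response %in% names(table)) stop_domain("no column '", response, "'")
  x <- table$pld; y <- table[[response]]
  keep <- is.finite(x) & is.finite(y)
  if (length(unique(x[keep])) < 3) {
    stop_domain("need at least 3 distinct PLD values")
  }
  fit <- stats::lm(y ~ x, subset = keep)
  sm <- summary(fit)
  structure(list(
    response = response,
    slope = unname(stats::coef(fit)[2]),
    se = unname(sm$coefficients[2, 2]),
    intercept = unname(stats::coef(fit)[1]),
    adj_r_squared = sm$adj.r.squared,
    p_value = unname(sm$coefficients[2, 4]),
    n = sum(keep)
  ), class = "pld_regression")
}

#' @export
print.pld_regression <- function(x, ...) {
  cat(sprintf("%s ~ PLD: slope %.4g +- %.2g per day, adj-R2 %.3f, p = %.3g (n = %d)\n",
              x$response, x$slope, x$se, x$adj_r_squared, x$p_value, x$n))
  invisible(x)
}

#' Two-sample Student's t-test between scenario replicates
#'
#' Pooled-variance two-sample t-test (the scenario replicates are
#' approximately normal with homogeneous variances). When both groups are
#' constant and equal the test is degenerate and reported as t = 0, p = 1.
#'
#' @param group_a,group_b numeric replicate vectors (>= 2 each).
#' @return list with \code{t}, \code{df}, \code{p_value}, \code{mean_a},
#'   \code{mean_b}, \code{sd_a}, \code{sd_b}.
#' @export
scenario_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_domain("need at least 2 replicates per group")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2,
                  p_value = 1, mean_a = mean(group_a), mean_b = mean(group_b),
                  sd_a = 0, sd_b = 0))
    }
    return(list(t = Inf * sign(mean(group_a) - mean(group_b)),
                df = length(group_a) + length(group_b) - 2, p_value = 0,
                mean_a = mean(group_a), mean_b = mean(group_b),
                sd_a = 0, sd_b = 0))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_a = mean(group_a), mean_b = mean(group_b),
       sd_a = stats::sd(group_a), sd_b = stats::sd(group_b))
}

#' One-way ANOVA across scenario groups
#'
#' Fixed-effects one-way ANOVA (e.g. spawning month July / August /
#' September). All-constant identical groups are degenerate and reported as
#' F = 0, p = 1.
#'
#' @param groups named list of numeric replicate vectors (>= 2 groups,
#'   >= 2 replicates each).
#' @return list with \code{f}, \code{df1}, \code{df2}, \code{p_value},
#'   \code{group_means}, \code{group_sds}.
#' @export
scenario_anova <- function(groups) {
  if (length(groups) < 2) stop_domain("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop_domain("need >= 2 replicates per group")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, stats::sd, numeric(1))
  df1 <- length(groups) - 1L; df2 <- length(y) - length(groups)
  if (stats::var(y) == 0) {
    return(list(f = 0, df1 = df1, df2 = df2, p_value = 1,
                group_means = means, group_sds = sds))
  }
  fit <- stats::aov(y ~ g)
  sm <- summary(fit)[[1]]
  list(f = sm[1, "F value"], df1 = df1, df2 = df2,
       p_value = sm[1, "Pr(>F)"], group_means = means, group_sds = sds)
}
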