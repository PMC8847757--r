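#' Define an experiment plan
#'
#' A plan bundles a base parameter set, sweep axes (named parameter grids,
#' crossed), the scenario set, an environment description, replicate count
#' and master seed.  Replicate `i` of every cell runs with seed
#' `seed + i` (`i = 1..reps`), so replicates are deterministic given the
#' master seed and cells share random numbers across conditions.
#'
#' @param params Base [sim_params()]; per-cell values from `sweep` and the
#'   scenario override it.
#' @param sweep Named list of value grids (e.g. `list(R00 = 1:8,
#'   bK = c(1, 3, 5))`); may be empty for a single-cell plan.
#' @param scenarios Character vector of scenarios to run; cells with
#'   `"non_structured"` automatically use `n_groups = 1`.
#' @param reps Replicates per cell.
#' @param seed Master seed.
#' @param schedule_kind `"constant"` (baseline `R00` of each cell) or
#'   `"sinusoidal"` (amplitude `A`, period `P` around each cell's `R00`).
#' @param A,P Sinusoidal amplitude and period (ignored for constant).
#' @param out_dir Optional output directory for per-replicate CSVs, the
#'   summary table and a JSON manifest.
#' @return An object of class `experiment_plan`.
#' @seealso [run_sweep()], [preset()]
#' @export
experiment_plan <- function(params = sim_params(), sweep = list(),
                            scenarios = "social", reps = 20, seed = 1,
                            schedule_kind = c("constant", "sinusoidal"),
                            A = 0, P = NA, out_dir = NULL) {
  schedule_kind <- match.arg(schedule_kind)
  if (length(sweep) && (is.null(names(sweep)) || any(names(sweep) == "")))
    stop("sweep axes must be named")
  for (g in sweep) if (!length(g)) stop("sweep grids must be non-empty")
  stopifnot(reps >= 1)
  structure(list(params = params, sweep = sweep, scenarios = scenarios,
                 reps = as.integer(reps), seed = as.integer(seed),
                 schedule_kind = schedule_kind, A = A, P = P,
                 out_dir = out_dir),
            class = "experiment_plan")
}

cell_schedule <- function(plan, R00) {
  if (plan$schedule_kind == "constant") env_constant(R00)
  else env_sinusoidal(R00, plan$A, plan$P)
}

cell_label <- function(row) {
  paste(vapply(names(row), function(nm) paste0(nm, "-", row[[nm]]),
               character(1)), collapse = "_")
}

#' Run an experiment sweep
#'
#' Executes [run_simulation()] for every sweep cell x scenario x replicate
#' of the plan and summarizes each cell on the stable window (default
#' second half): cross-replicate means and sds of the stable-window mean
#' population size, proportion of cooperators and mean cooperation degree,
#' plus the fraction of replicates extinct by the final step.  Given the
#' same plan the output (including written files) is byte-identical.
#'
#' @param plan An [experiment_plan()].
#' @param burn_in Burn-in fraction for the stable window.
#' @return A data.frame of class `sweep_summary`: one row per cell, with
#'   the sweep-axis values, `scenario`, `reps`, `mean_N`, `sd_N`,
#'   `mean_prop_coop`, `sd_prop_coop`, `mean_degree`, `sd_degree` and
#'   `extinct_frac`.  When the plan has an `out_dir`, per-replicate series
#'   CSVs, `summary.csv` and `manifest.json` are written there.
#' @export
run_sweep <- function(plan, burn_in = 0.5) {
  stopifnot(inherits(plan, "experiment_plan"))
  axes <- c(plan$sweep, list(scenario = plan$scenarios))
  grid <- expand.grid(axes, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  out_dir <- plan$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, , drop = FALSE]
    overrides <- as.list(cell)
    if (identical(overrides$scenario, "non_structured"))
      overrides$n_groups <- 1L
    p <- do.call(update_params, c(list(plan$params), overrides))
    sch <- cell_schedule(plan, p$R00)
    stat <- matrix(NA_real_, nrow = plan$reps, ncol = 4)
    for (i in seq_len(plan$reps)) {
      ser <- run_simulation(p, sch, seed = plan$seed + i)
      w <- stable_window(ser, burn_in)
      stat[i, ] <- c(mean(w$N), mean(w$prop_coop), mean(w$mean_degree),
                     as.numeric(ser$N[nrow(ser)] == 0L))
      if (!is.null(out_dir))
        write_series_csv(ser, file.path(out_dir,
          sprintf("%s_rep%03d.csv", cell_label(cell), i)))
    }
    rows[[g]] <- cbind(cell,
      data.frame(reps = plan$reps,
                 mean_N = mean(stat[, 1]), sd_N = stats::sd(stat[, 1]),
                 mean_prop_coop = mean(stat[, 2]),
                 sd_prop_coop = stats::sd(stat[, 2]),
                 mean_degree = mean(stat[, 3]),
                 sd_degree = stats::sd(stat[, 3]),
                 extinct_frac = mean(stat[, 4])))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  class(summary) <- c("sweep_summary", "data.frame")
  if (!is.null(out_dir)) {
    write_series_csv(summary, file.path(out_dir, "summary.csv"))
    manifest <- list(
      package = "coopdyn",
      version = as.character(utils::packageVersion("coopdyn")),
      params = unclass(plan$params),
      sweep = plan$sweep, scenarios = plan$scenarios,
      reps = plan$reps, master_seed = plan$seed,
      replicate_seeds = plan$seed + seq_len(plan$reps),
      schedule = list(kind = plan$schedule_kind, A = plan$A, P = plan$P),
      burn_in = burn_in)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  summary
}

#' Experiment presets
#'
#' Ready-made plans for the model's standard experiment designs:
#' \describe{
#'   \item{`fig2`}{proportion-of-cooperators surface over the resource
#'     availability x cooperation efficiency grid (`R00 = 1..8`,
#'     `bK = 1..5`), social scenario.}
#'   \item{`fig3`}{cooperation (proportion and mean degree) vs. `R00` at
#'     low/medium/high efficiency (`bK = 1, 3, 5`), social scenario.}
#'   \item{`fig5`}{population size vs. `R00` at `bK = 1, 3, 5` for social
#'     and non-social populations (the niche-width comparison).}
#'   \item{`fig6`}{sinusoidally forced environment (`R00 = 4`, `A = 2.5`,
#'     `P = 500`), social (`bK = 5`) and non-social populations, for the
#'     synchrony (TLCC) and variability (spectrum) analyses.}
#'   \item{`nonstructured_control`}{single well-mixed group at harsh
#'     `R00 = 1`, `bK = 5`: the control in which cooperation cannot
#'     evolve.}
#' }
#'
#' @param name Preset name.
#' @param scale `"desk"` (T = 2000 steps, 20 replicates; minutes) or
#'   `"paper"` (T = 10000 steps, 500 replicates; hours).
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @return An [experiment_plan()].
#' @export
preset <- function(name = c("fig2", "fig3", "fig5", "fig6",
                            "nonstructured_control"),
                   scale = c("desk", "paper"), seed = 1, out_dir = NULL) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  T <- if (scale == "paper") 10000L else 2000L
  reps <- if (scale == "paper") 500L else 20L
  base <- sim_params(T = T)
  switch(name,
    fig2 = experiment_plan(base, sweep = list(R00 = 1:8, bK = 1:5),
                           scenarios = "social", reps = reps, seed = seed,
                           out_dir = out_dir),
    fig3 = experiment_plan(base, sweep = list(R00 = 1:8, bK = c(1, 3, 5)),
                           scenarios = "social", reps = reps, seed = seed,
                           out_dir = out_dir),
    fig5 = experiment_plan(base, sweep = list(R00 = 1:8, bK = c(1, 3, 5)),
                           scenarios = c("social", "non_social"),
                           reps = reps, seed = seed, out_dir = out_dir),
    fig6 = experiment_plan(update_params(base, R00 = 4, bK = 5),
                           scenarios = c("social", "non_social"),
                           reps = reps, seed = seed,
                           schedule_kind = "sinusoidal", A = 2.5, P = 500,
                           out_dir = out_dir),
    nonstructured_control =
      experiment_plan(update_params(base, R00 = 1, bK = 5, n_groups = 1L),
                      scenarios = "non_structured", reps = reps,
                      seed = seed, out_dir = out_dir))
}

#' Calibration smoke test for the default parameters
#'
#' Verifies with short replicate runs that the shipped life-cycle defaults
#' place the harsh and benign baselines on the intended sides of the
#' persistence boundary: (a) non-social populations persist at the benign
#' baseline, (b) non-social populations go extinct at the harsh baseline,
#' and (c) social populations with the plan's cooperation efficiency
#' persist at the harsh baseline.  Each criterion requires at least 90% of
#' replicates.  Failing criteria are reported, not raised.
#'
#' @param params Base [sim_params()] (its `bK` is used for criterion c).
#' @param harsh_R00,benign_R00 Harsh and benign baselines
#'   (`harsh_R00 < benign_R00`).
#' @param reps Replicates per condition.
#' @param T Steps per run.
#' @param seed Master seed.
#' @return A data.frame of class `calibration_report` with one row per
#'   criterion: `criterion`, `description`, `fraction` (of replicates
#'   meeting the condition), `threshold` and `pass`.
#' @export
calibrate <- function(params = sim_params(), harsh_R00 = 1, benign_R00 = 8,
                      reps = 20, T = 2000, seed = 1) {
  if (!(harsh_R00 < benign_R00))
    stop("invalid parameter: harsh_R00 must be below benign_R00")
  persists <- function(p) {
    mean(vapply(seq_len(reps), function(i) {
      ser <- run_simulation(p, seed = seed + i)
      ser$N[nrow(ser)] > 0L
    }, logical(1)))
  }
  pa <- persists(update_params(params, R00 = benign_R00, T = T,
                               scenario = "non_social"))
  pb <- 1 - persists(update_params(params, R00 = harsh_R00, T = T,
                                   scenario = "non_social"))
  pc <- persists(update_params(params, R00 = harsh_R00, T = T,
                               scenario = "social"))
  out <- data.frame(
    criterion = c("a", "b", "c"),
    description = c(
      sprintf("non-social persists at benign R00 = %g", benign_R00),
      sprintf("non-social goes extinct at harsh R00 = %g", harsh_R00),
      sprintf("social (bK = %g) persists at harsh R00 = %g",
              params$bK, harsh_R00)),
    fraction = c(pa, pb, pc),
    threshold = 0.9)
  out$pass <- out$fraction >= out$threshold
  class(out) <- c("calibration_report", "data.frame")
  out
}

#' Read an experiment plan from a YAML config file
#'
#' The config mirrors the plan structure: a `params` section
#' (any [sim_params()] field), an optional `schedule` section (`kind`,
#' `A`, `P`) and a `plan` section (`sweep`, `scenarios`, `reps`, `seed`,
#' `out_dir`).  See `system.file("extdata", "example_config.yaml",
#' package = "coopdyn")`.
#'
#' @param path Path to a YAML file.
#' @return An [experiment_plan()].
#' @export
read_plan_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- do.call(sim_params, cfg$params %||% list())
  sch <- cfg$schedule %||% list()
  plan <- cfg$plan %||% list()
  experiment_plan(
    params = params,
    sweep = plan$sweep %||% list(),
    scenarios = unlist(plan$scenarios %||% params$scenario),
    reps = plan$reps %||% 20,
    seed = plan$seed %||% 1,
    schedule_kind = sch$kind %||% "constant",
    A = sch$A %||% 0, P = sch$P %||% NA,
    out_dir = plan$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
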