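# Run orchestration: config-driven solves with plain-text artifacts
# (trajectory/front CSVs, objective/multiplier JSON, convergence history,
# reproducibility manifest). All outputs are CSV/JSON; the seed and resolved
# configuration are recorded in every manifest.

resolve_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(problem = NULL, strategy = "two_phase", objective = 1L,
                   seed = 1L, output_dir = "dynenz_run", settings = list(),
                   log_level = "info")
  config <- utils::modifyList(defaults, config)
  if (is.null(config$problem)) stop("config needs a 'problem' entry")
  ok_strategies <- c("two_phase", "cvp_hybrid", "collocation",
                     "multistart_collocation")
  if (!config$strategy %in% ok_strategies)
    stop("unknown strategy '", config$strategy, "'")
  config
}

resolve_problem <- function(ref) {
  if (is.character(ref)) {
    if (file.exists(ref)) load_ocp(ref) else get_benchmark(ref)
  } else if (inherits(ref, "ocp_problem")) ref
  else list_to_problem(ref)
}

write_manifest <- function(dir, config, extra = list()) {
  manifest <- c(list(
    tool = "dynenz",
    version = as.character(utils::packageVersion("dynenz")),
    seed = config$seed,
    config = config[setdiff(names(config), "output_dir")]),
    extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

write_solution_artifacts <- function(sol, dir, prefix = "solution") {
  utils::write.csv(as.data.frame(sol),
                   file.path(dir, paste0(prefix, "_trajectory.csv")),
                   row.names = FALSE)
  info <- list(objectives = as.list(sol$objectives), cost = sol$cost,
               feasible = sol$feasible, violation = sol$viol,
               strategy = sol$strategy, seed = sol$seed,
               tf = sol$traj$tf)
  if (!is.null(sol$adjoints)) {
    info$constraint_sensitivity <- as.list(sol$adjoints$sensitivity)
    adf <- data.frame(time = sol$adjoints$times, sol$adjoints$lambda,
                      check.names = FALSE)
    utils::write.csv(adf, file.path(dir, paste0(prefix, "_adjoints.csv")),
                     row.names = FALSE)
    if (ncol(sol$adjoints$mu))
      utils::write.csv(
        data.frame(time = sol$adjoints$times, sol$adjoints$mu,
                   check.names = FALSE),
        file.path(dir, paste0(prefix, "_path_multipliers.csv")),
        row.names = FALSE)
  }
  jsonlite::write_json(info, file.path(dir, paste0(prefix, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(sol$history))
    utils::write.csv(as.data.frame(sol$history),
                     file.path(dir, paste0(prefix, "_history.csv")),
                     row.names = FALSE)
  invisible(dir)
}

#' Run a single-objective solve from a config
#'
#' @param config list or path to a YAML/JSON run config with entries
#'   \code{problem} (benchmark name or problem config path), \code{strategy},
#'   \code{objective}, \code{seed}, \code{output_dir}, \code{settings}.
#' @return the \code{ocp_solution}, invisibly; artifacts (trajectory CSV,
#'   objectives/multipliers JSON, history CSV, manifest) in
#'   \code{output_dir}.
#' @export
run_solve <- function(config) {
  config <- resolve_run_config(config)
  problem <- resolve_problem(config$problem)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  sol <- solve_ocp(problem, strategy = config$strategy,
                   objective = config$objective, seed = config$seed,
                   settings = config$settings)
  write_solution_artifacts(sol, config$output_dir)
  write_manifest(config$output_dir, config,
                 list(feasible = sol$feasible, cost = sol$cost))
  invisible(sol)
}

#' Trace a Pareto front from a config
#'
#' @param config as in \code{\link{run_solve}}.
#' @param n_points number of front points.
#' @return the \code{pareto_front}, invisibly; front CSV plus per-point
#'   trajectory CSVs in \code{output_dir}.
#' @export
run_pareto <- function(config, n_points = 11L) {
  config <- resolve_run_config(config)
  problem <- resolve_problem(config$problem)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  front <- epsilon_constraint_sweep(problem,
                                    primary_index = config$objective,
                                    n_points = n_points,
                                    strategy = config$strategy,
                                    seed = config$seed,
                                    settings = config$settings)
  utils::write.csv(as.data.frame(front),
                   file.path(config$output_dir, "front.csv"),
                   row.names = FALSE)
  for (i in seq_along(front$solutions)) {
    pdir <- file.path(config$output_dir, sprintf("point_%02d", i))
    dir.create(pdir, showWarnings = FALSE)
    write_solution_artifacts(front$solutions[[i]], pdir)
  }
  write_manifest(config$output_dir, config,
                 list(n_points = nrow(front$objectives)))
  invisible(front)
}

#' Run a post-optimality analysis from a config
#'
#' @param config as in \code{\link{run_solve}}.
#' @param mode \code{"ensemble"}, \code{"sweep"} or \code{"sensitivity"}.
#' @param mode_args list of mode-specific arguments: ensemble
#'   (\code{n_runs}, \code{threshold}); sweep (\code{constraint_label},
#'   \code{values}, \code{sweep_mode}); sensitivity (none).
#' @return the analysis object, invisibly; CSV/JSON artifacts in
#'   \code{output_dir}.
#' @export
run_analysis <- function(config, mode = c("ensemble", "sweep", "sensitivity"),
                         mode_args = list()) {
  mode <- match.arg(mode)
  config <- resolve_run_config(config)
  problem <- resolve_problem(config$problem)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(mode,
    ensemble = {
      ens <- do.call(multiplicity_ensemble,
                     c(list(problem = problem, strategy = config$strategy,
                            seed = config$seed, settings = config$settings,
                            objective = config$objective), mode_args))
      for (nm in names(ens$control_envelopes))
        utils::write.csv(ens$control_envelopes[[nm]],
                         file.path(config$output_dir,
                                   sprintf("envelope_control_%s.csv", nm)),
                         row.names = FALSE)
      for (nm in names(ens$state_envelopes))
        utils::write.csv(ens$state_envelopes[[nm]],
                         file.path(config$output_dir,
                                   sprintf("envelope_state_%s.csv", nm)),
                         row.names = FALSE)
      jsonlite::write_json(
        list(best_cost = ens$best_cost, costs = ens$costs,
             member = ens$member, seeds = ens$seeds,
             histogram = list(breaks = ens$cost_histogram$breaks,
                              counts = ens$cost_histogram$counts)),
        file.path(config$output_dir, "ensemble.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      ens
    },
    sweep = {
      sw <- do.call(constraint_sweep,
                    c(list(problem = problem, strategy = config$strategy,
                           seed = config$seed, settings = config$settings,
                           objective = config$objective), mode_args))
      utils::write.csv(sw$summary,
                       file.path(config$output_dir, "sweep_summary.csv"),
                       row.names = FALSE)
      for (i in seq_along(sw$results)) {
        vdir <- file.path(config$output_dir,
                          sprintf("value_%g", sw$values[i]))
        dir.create(vdir, showWarnings = FALSE)
        if (sw$mode == "anchor")
          write_solution_artifacts(sw$results[[i]], vdir)
        else
          utils::write.csv(as.data.frame(sw$results[[i]]),
                           file.path(vdir, "front.csv"), row.names = FALSE)
      }
      sw
    },
    sensitivity = {
      sol <- solve_ocp(problem, strategy = config$strategy,
                       objective = config$objective, seed = config$seed,
                       settings = config$settings)
      rep <- sensitivity_report(sol)
      utils::write.csv(rep,
                       file.path(config$output_dir, "sensitivity.csv"),
                       row.names = FALSE)
      rep
    })
  write_manifest(config$output_dir, config, list(mode = mode))
  invisible(out)
}
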