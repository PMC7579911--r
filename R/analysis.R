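# Post-optimality analyses: near-optimal solution multiplicity, constraint
# sweeps, and multiplier-based sensitivity ranking.

#' Near-optimal solution-multiplicity ensemble
#'
#' Repeats a solve with consecutive seeds, keeps the runs whose cost lies
#' within a relative threshold of the best (default 0.5 percent), and
#' summarizes the spread of controls and states as min/median/max envelopes
#' on a common 200-point normalized-time grid. Wide control envelopes at a
#' near-zero cost spread indicate control multiplicity (e.g. highly
#' correlated controls that can compensate for each other).
#'
#' @param problem an \code{ocp_problem}.
#' @param strategy solver strategy.
#' @param n_runs number of runs (>= 2), seeds \code{seed .. seed+n_runs-1}.
#' @param threshold relative cost threshold for ensemble membership.
#' @param seed base seed.
#' @param settings forwarded to \code{\link{solve_ocp}}.
#' @param objective objective index for the scalar solves.
#' @return an \code{ensemble_summary}: best cost, member costs and seeds,
#'   control/state envelopes, cost histogram.
#' @export
multiplicity_ensemble <- function(problem, strategy = "two_phase",
                                  n_runs = 10L, threshold = 0.005,
                                  seed = 1L, settings = list(),
                                  objective = 1L) {
  stopifnot(n_runs >= 2L)
  runs <- lapply(seq_len(n_runs) - 1L, function(k)
    tryCatch(solve_ocp(problem, strategy = strategy, objective = objective,
                       seed = seed + k, settings = settings),
             error = function(e) NULL))
  ok <- vapply(runs, function(r) !is.null(r) && r$feasible, TRUE)
  if (!any(ok)) stop("no ensemble: all runs failed or ended infeasible")
  runs <- runs[ok]
  costs <- vapply(runs, `[[`, 0, "cost")
  best <- min(costs)
  # relative threshold on the scalarized cost; |best| guards sign
  cutoff <- best + threshold * abs(best)
  member <- costs <= cutoff + .Machine$double.eps^0.5
  members <- runs[member]
  grid <- seq(0, 1, length.out = 200L)
  env_of <- function(get) {
    mats <- lapply(members, function(r) {
      tt <- r$traj$times
      tau <- (tt - tt[1]) / (tt[length(tt)] - tt[1])
      vals <- get(r)
      apply(vals, 2L, function(v) stats::approx(tau, v, xout = grid)$y)
    })
    nms <- colnames(get(members[[1]]))
    arr <- simplify2array(mats)   # grid x var x member
    if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
    lapply(stats::setNames(seq_along(nms), nms), function(j)
      data.frame(tau = grid,
                 min = apply(arr[, j, , drop = FALSE], 1L, min),
                 median = apply(arr[, j, , drop = FALSE], 1L, stats::median),
                 max = apply(arr[, j, , drop = FALSE], 1L, max)))
  }
  structure(list(
    best_cost = best, threshold = threshold, cutoff = cutoff,
    costs = costs, seeds = seed + which(ok) - 1L,
    member = member, n_members = sum(member),
    control_envelopes = env_of(function(r) r$traj$controls),
    state_envelopes = env_of(function(r) r$traj$states),
    cost_histogram = graphics::hist(costs, plot = FALSE),
    members = members), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Solution-multiplicity ensemble: ", length(x$costs), " runs, ",
      x$n_members, " within ", 100 * x$threshold, "% of best cost ",
      signif(x$best_cost, 8), "\n", sep = "")
  spread <- vapply(x$control_envelopes, function(e) max(e$max - e$min), 0)
  cat("  max control envelope widths:\n")
  for (nm in names(spread)) cat(sprintf("    %-10s %.4g\n", nm, spread[nm]))
  invisible(x)
}

#' Re-solve under varied constraint bounds (critical-value sweep)
#'
#' Re-solves the anchor problem (or retraces the whole front) for each value
#' of a named constraint's bound, e.g. the critical ATP value of the survival
#' constraints. Tightening a constraint can never improve the optimum
#' (nested feasible sets), which the sweep exposes.
#'
#' @param problem an \code{ocp_problem}.
#' @param constraint_label label of a path or point constraint.
#' @param values bound values to sweep.
#' @param mode \code{"anchor"} (single-objective re-solve) or \code{"front"}.
#' @param strategy,seed,settings solver configuration.
#' @param objective objective index for anchor mode.
#' @param n_points front size for front mode.
#' @return a \code{constraint_sweep} object: per-value results and a summary
#'   data.frame.
#' @export
constraint_sweep <- function(problem, constraint_label, values,
                             mode = c("anchor", "front"),
                             strategy = "two_phase", seed = 1L,
                             settings = list(), objective = 1L,
                             n_points = 7L) {
  mode <- match.arg(mode)
  if (!length(values)) stop("nothing to sweep: empty values")
  set_bound <- function(prob, value) {
    hit <- FALSE
    for (i in seq_along(prob$path_constraints)) {
      if (prob$path_constraints[[i]]$label == constraint_label) {
        prob$path_constraints[[i]]$bound <- value; hit <- TRUE
      }
    }
    for (i in seq_along(prob$point_constraints)) {
      if (prob$point_constraints[[i]]$label == constraint_label) {
        prob$point_constraints[[i]]$bound <- value; hit <- TRUE
      }
    }
    if (!hit) stop("no constraint labelled '", constraint_label, "'")
    compile_problem(prob)
  }
  results <- lapply(values, function(v) {
    pv <- set_bound(problem, v)
    if (mode == "anchor")
      solve_ocp(pv, strategy = strategy, objective = objective, seed = seed,
                settings = settings)
    else
      epsilon_constraint_sweep(pv, primary_index = objective,
                               n_points = n_points, strategy = strategy,
                               seed = seed, settings = settings)
  })
  summary <- if (mode == "anchor")
    data.frame(value = values,
               cost = vapply(results, `[[`, 0, "cost"),
               feasible = vapply(results, `[[`, TRUE, "feasible"),
               t(vapply(results, `[[`, results[[1]]$objectives, "objectives")))
  else
    data.frame(value = values,
               n_points = vapply(results, function(f) nrow(f$objectives), 0L))
  structure(list(label = constraint_label, values = values, mode = mode,
                 results = results, summary = summary),
            class = "constraint_sweep")
}

#' @export
print.constraint_sweep <- function(x, ...) {
  cat("Constraint sweep on '", x$label, "' (", x$mode, " mode)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Multiplier-based constraint sensitivity report
#'
#' Ranks the constraints of a converged collocation solve by the magnitude of
#' their Lagrange multipliers: path constraints by the integral of the
#' multiplier density |mu| over the horizon, point constraints by their
#' scalar |multiplier|, and control bounds by the summed bound multipliers.
#' Like a shadow price, each entry estimates how much the optimal cost would
#' improve per unit of constraint relaxation.
#'
#' @param solution an \code{ocp_solution} from a collocation-based strategy
#'   (carries a multiplier set).
#' @return data.frame ranked by sensitivity: constraint, type, sensitivity,
#'   activity fraction of the horizon.
#' @export
sensitivity_report <- function(solution) {
  if (is.null(solution$mult))
    stop("sensitivity_report needs a collocation-based solution with multipliers")
  mult <- solution$mult
  canonical <- solution$canonical
  mesh <- solution$mesh
  rows <- list()
  cc <- check_constraints(canonical, solution$traj)
  for (k in seq_len(ncol(mult$path))) {
    lab <- colnames(mult$path)[k]
    rows[[length(rows) + 1L]] <- data.frame(
      constraint = lab, type = "path",
      sensitivity = sum(abs(mult$path[, k])),
      max_multiplier = max(abs(mult$path[, k])),
      activity = cc$active_fraction[cc$label == lab][1])
  }
  pt_eq <- Filter(function(p) p$rel == "==", canonical$point_constraints)
  pt_in <- Filter(function(p) p$rel != "==", canonical$point_constraints)
  for (k in seq_along(pt_eq))
    rows[[length(rows) + 1L]] <- data.frame(
      constraint = pt_eq[[k]]$label, type = "point",
      sensitivity = abs(mult$point_eq[k]),
      max_multiplier = abs(mult$point_eq[k]), activity = 1)
  for (k in seq_along(pt_in))
    rows[[length(rows) + 1L]] <- data.frame(
      constraint = pt_in[[k]]$label, type = "point",
      sensitivity = abs(mult$point_in[k]),
      max_multiplier = abs(mult$point_in[k]),
      activity = as.numeric(abs(mult$point_in[k]) > 1e-10))
  if (any(mult$bound != 0)) {
    lay <- solution$cvp_par
    nuc <- n_controls(canonical)
    Np <- length(mesh$nodes)
    ns <- n_states(canonical)
    for (j in seq_len(nuc)) {
      idx <- ns * Np + (j - 1L) * Np + seq_len(Np)
      bm <- mult$bound[idx]
      if (any(bm != 0))
        rows[[length(rows) + 1L]] <- data.frame(
          constraint = paste0("bounds_", canonical$controls[j]),
          type = "control_bound",
          sensitivity = sum(abs(bm)), max_multiplier = max(abs(bm)),
          activity = mean(bm != 0))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$sensitivity), ]
  rownames(out) <- NULL
  out$note <- "shadow price: expected cost change per unit bound relaxation"
  out
}
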