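# Multi-objective driver: epsilon-constraint scalarization.
#
# The Pareto set is traced by solving a family of single-objective problems:
# anchors first (each objective optimized alone), then, for each epsilon on a
# uniform grid spanning the secondary objective between its anchor values,
# the primary objective is optimized subject to the secondary being at least
# as good as epsilon. Since every solver works on the canonical augmented
# form, a secondary objective is an endpoint expression (quadrature state or
# the tf parameter), and the epsilon constraint is just an extra point
# constraint at tf.

#' Solve a single-objective anchor problem
#'
#' @param problem an \code{ocp_problem}.
#' @param objective_index which objective to optimize.
#' @param strategy solver strategy (see \code{\link{solve_ocp}}).
#' @param seed integer seed.
#' @param settings forwarded to \code{\link{solve_ocp}}.
#' @param init optional warm start.
#' @return an \code{ocp_solution}.
#' @export
solve_anchor <- function(problem, objective_index = 1L,
                         strategy = "two_phase", seed = 1L,
                         settings = list(), init = NULL) {
  solve_ocp(problem, strategy = strategy, objective = objective_index,
            seed = seed, settings = settings, init = init)
}

# epsilon constraint on objective k of the canonical problem: its endpoint
# value must be at least as good as eps (<= eps when minimized, >= eps when
# maximized).
add_epsilon_constraint <- function(canonical, k, eps) {
  ob <- canonical$objectives[[k]]
  rel <- if (ob$sense == "min") "<=" else ">="
  pc <- point_constraint(ob$mayer_text, time = "tf", bound = eps, rel = rel,
                         label = sprintf("epsilon_J%d", k))
  canonical$point_constraints <- c(canonical$point_constraints, list(pc))
  compile_problem(canonical)
}

#' Trace the Pareto front with the epsilon-constraint method
#'
#' @param problem a multi-objective \code{ocp_problem} (two objectives
#'   supported).
#' @param primary_index objective kept as the scalar cost; the other is
#'   bounded by epsilon.
#' @param n_points number of front points (including the two anchors).
#' @param strategy solver strategy per point.
#' @param seed integer seed (each subproblem k uses seed + k).
#' @param settings forwarded to \code{\link{solve_ocp}}.
#' @param warm_start continue each solve from its epsilon-neighbor (default);
#'   set FALSE to force independent cold starts (multiplicity studies).
#' @param phase1_front optional \code{pareto_front} computed with
#'   \code{strategy = "cvp_hybrid"} on the same problem and seed: with
#'   \code{strategy = "two_phase"} the deterministic phase-1 sweep is not
#'   recomputed; each stored phase-1 point is refined by the collocation
#'   phase directly.
#' @param verbose print per-stage timing while sweeping.
#' @param interior_max_evals optional smaller search budget for the
#'   warm-started interior points (they lean on the continuation polish;
#'   exploration is the anchors' job).
#' @return an object of class \code{pareto_front}.
#' @export
epsilon_constraint_sweep <- function(problem, primary_index = 1L,
                                     n_points = 11L,
                                     strategy = "two_phase", seed = 1L,
                                     settings = list(), warm_start = TRUE,
                                     phase1_front = NULL, verbose = FALSE,
                                     interior_max_evals = NULL) {
  if (!is.null(phase1_front)) {
    if (!identical(strategy, "two_phase"))
      stop("phase1_front reuse is only meaningful for the two_phase strategy")
    return(refine_front_collocation(problem, phase1_front, primary_index,
                                    seed, settings))
  }
  Nobj <- n_objectives(problem)
  if (Nobj < 2L) stop("epsilon-constraint sweep needs at least two objectives")
  if (Nobj > 2L) stop("only bi-objective problems are supported")
  stopifnot(n_points >= 2L)
  sec <- setdiff(seq_len(Nobj), primary_index)[1]

  say <- function(...) if (verbose) { cat(...); utils::flush.console() }
  t_stage <- function() round(as.numeric(Sys.time()), 1)
  t0 <- Sys.time()
  anchors <- lapply(seq_len(Nobj), function(k)
    solve_anchor(problem, k, strategy = strategy, seed = seed + k,
                 settings = settings))
  say("anchors:", round(as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      "s\n")
  for (k in seq_len(Nobj)) {
    if (!anchors[[k]]$feasible)
      warning("anchor for objective ", k, " did not reach feasibility")
  }
  # secondary objective value at its own anchor (best) and at the primary
  # anchor (worst end of the trade-off)
  eps_best <- anchors[[sec]]$objectives[sec]
  eps_worst <- anchors[[primary_index]]$objectives[sec]
  # lexicographic secondary anchor: among solutions attaining the anchor
  # value of the secondary objective, optimize the primary one — the plain
  # anchor leaves the primary coordinate in a flat, solver-dependent
  # direction, which would make the front's end point ill-defined
  t0 <- Sys.time()
  lex <- tryCatch(
    solve_ocp_epsilon(problem, sec, eps_best, primary_index,
                      strategy = strategy, seed = seed + Nobj + n_points,
                      settings = settings, init = anchors[[sec]]),
    error = function(e) NULL)
  if (!is.null(lex) && lex$feasible) {
    sgn_p0 <- if (problem$objectives[[primary_index]]$sense == "max") -1 else 1
    if (sgn_p0 * lex$objectives[primary_index] <=
        sgn_p0 * anchors[[sec]]$objectives[primary_index] + 1e-9)
      anchors[[sec]] <- lex
  }
  eps_grid <- seq(eps_worst, eps_best, length.out = n_points)
  # interior points only; anchors provide the endpoints
  interior <- if (n_points > 2L) eps_grid[2:(n_points - 1L)] else numeric(0)

  sols <- vector("list", n_points)
  sols[[1L]] <- anchors[[primary_index]]
  sols[[n_points]] <- anchors[[sec]]
  eps_used <- rep(NA_real_, n_points)
  eps_used[1L] <- eps_worst; eps_used[n_points] <- eps_best
  # continuation runs from the secondary anchor outward: relaxing epsilon
  # step by step keeps every warm start feasible for its subproblem, so each
  # solve is a descent to the new constraint boundary (restoring feasibility
  # from the violated side is much harder for the local phase)
  prev <- anchors[[sec]]
  anchor_ys <- Filter(Negate(is.null), lapply(anchors, `[[`, "cvp_y"))
  say("lex anchor:",
      round(as.numeric(difftime(Sys.time(), t0, units = "secs"))), "s\n")
  for (i in rev(seq_along(interior))) {
    eps <- interior[i]
    t0 <- Sys.time()
    st_i <- settings
    # warm-started continuation points lean on the polish; exploration is
    # the anchors' job, so their search budget can be much smaller
    if (!is.null(interior_max_evals))
      st_i$search$max_evals <- interior_max_evals
    same_len <- vapply(anchor_ys, length, 0L)
    if (length(anchor_ys) && length(unique(same_len)) == 1L)
      st_i$search$init_points <- do.call(rbind, anchor_ys)
    # carry the neighbor's AL multipliers: the shadow price of the epsilon
    # constraint changes slowly along the front
    if (warm_start && !is.null(prev$cvp_mult))
      st_i$search$warm_mult <- prev$cvp_mult
    s <- tryCatch(
      solve_ocp_epsilon(problem, sec, eps, primary_index,
                        strategy = strategy, seed = seed + Nobj + i,
                        settings = st_i,
                        init = if (warm_start) prev else NULL),
      error = function(e) {
        warning("epsilon subproblem at eps = ", signif(eps, 6),
                " failed: ", conditionMessage(e))
        NULL
      })
    # stall detection: a warm-started solve that did not move away from its
    # neighbor although the epsilon constraint has plenty of slack is re-run
    # cold with the full diversification of the global phase
    sgn_p <- if (problem$objectives[[primary_index]]$sense == "max") -1 else 1
    stalled <- warm_start && !is.null(s) && s$feasible &&
      max(abs(s$objectives - prev$objectives)) < 1e-6 &&
      abs(s$objectives[sec] - eps) >
        1e-3 * max(1, abs(eps_best - eps_worst))
    if (stalled) {
      s_cold <- tryCatch(
        solve_ocp_epsilon(problem, sec, eps, primary_index,
                          strategy = strategy, seed = seed + Nobj + i + 5000L,
                          settings = settings, init = NULL),
        error = function(e) NULL)
      if (!is.null(s_cold) && s_cold$feasible &&
          sgn_p * s_cold$objectives[primary_index] <
            sgn_p * s$objectives[primary_index] - 1e-9)
        s <- s_cold
    }
    say("eps ", signif(eps, 6), ": ",
        round(as.numeric(difftime(Sys.time(), t0, units = "secs"))), "s",
        if (stalled) " (stall fallback)", "\n", sep = "")
    if (!is.null(s) && s$feasible) {
      sols[[1L + i]] <- s
      eps_used[1L + i] <- eps
      if (warm_start) prev <- s
    } else if (!is.null(s)) {
      warning("epsilon subproblem at eps = ", signif(eps, 6),
              " infeasible; point dropped")
    }
  }
  keep <- !vapply(sols, is.null, TRUE)
  sols <- sols[keep]; eps_used <- eps_used[keep]
  build_pareto_front(problem, sols, eps_used,
                     anchor_flags = c(TRUE, rep(FALSE, length(sols) - 2L), TRUE))
}

# collocation refinement of a stored phase-1 front (two_phase with the
# deterministic CVP sweep memoized)
refine_front_collocation <- function(problem, phase1, primary_index, seed,
                                     settings) {
  Nobj <- n_objectives(problem)
  sec <- setdiff(seq_len(Nobj), primary_index)[1]
  sols <- vector("list", length(phase1$solutions))
  for (i in seq_along(phase1$solutions)) {
    s1 <- phase1$solutions[[i]]
    obj <- s1$objective
    canonical <- prepare_problem(problem)
    # refine with the epsilon constraint whenever the stored point was a
    # primary-objective solve (includes the lexicographic secondary anchor)
    if (!is.na(phase1$eps[i]) && obj == primary_index)
      canonical <- add_epsilon_constraint(canonical, sec, phase1$eps[i])
    s2 <- tryCatch(
      solve_prepared(problem, canonical, "collocation", obj, seed + i,
                     settings, init = s1),
      error = function(e) NULL)
    if (!is.null(s2)) {
      pick <- choose_two_phase(s1, s2, obj, canonical)
      pick$strategy <- "two_phase"
      sols[[i]] <- pick
    } else {
      sols[[i]] <- s1   # keep the feasible phase-1 point
    }
  }
  build_pareto_front(problem, sols, phase1$eps,
                     anchor_flags = seq_along(sols) %in% phase1$anchors)
}

# solve with an epsilon constraint injected at the canonical level
solve_ocp_epsilon <- function(problem, sec, eps, primary_index, strategy,
                              seed, settings, init) {
  prob_eps <- problem
  attr(prob_eps, "add_epsilon") <- list(k = sec, eps = eps)
  # inject by wrapping prepare: easiest is to pre-augment here
  canonical <- add_epsilon_constraint(prepare_problem(problem), sec, eps)
  solve_prepared(problem, canonical, strategy, primary_index, seed, settings,
                 init)
}

# like solve_ocp but with an externally supplied canonical problem
solve_prepared <- function(problem, canonical, strategy, objective, seed,
                           settings, init = NULL) {
  st <- utils::modifyList(solve_settings_defaults(), settings)
  if (is.null(st$cvp$variable_length))
    st$cvp$variable_length <- FALSE
  sol <- switch(strategy,
    cvp_hybrid = solve_cvp_phase(problem, canonical, objective, seed, st, init),
    two_phase = {
      s1 <- solve_cvp_phase(problem, canonical, objective, seed, st, init)
      s2 <- solve_colloc_phase(problem, canonical, objective, seed, st,
                               init = s1)
      choose_two_phase(s1, s2, objective, canonical)
    },
    collocation = solve_colloc_phase(problem, canonical, objective, seed, st,
                                     init = init),
    multistart_collocation = solve_colloc_phase(problem, canonical, objective,
                                                seed, st, init = init,
                                                multistart = TRUE),
    stop("unknown strategy '", strategy, "'"))
  sol$strategy <- strategy
  sol$seed <- seed
  sol$settings <- st
  sol
}

build_pareto_front <- function(problem, sols, eps_used, anchor_flags) {
  J <- do.call(rbind, lapply(sols, function(s)
    s$objectives[seq_len(n_objectives(problem))]))
  senses <- vapply(problem$objectives, `[[`, "", "sense")
  # dominance filtering in all-minimization convention
  Jmin <- sweep(J, 2L, ifelse(senses == "max", -1, 1), `*`)
  keep <- attr(filter_dominated(Jmin), "indices")
  sols <- sols[keep]; J <- J[keep, , drop = FALSE]
  eps_used <- eps_used[keep]; anchor_flags <- anchor_flags[keep]
  ord <- order(J[, 1L])
  sols <- sols[ord]; J <- J[ord, , drop = FALSE]
  eps_used <- eps_used[ord]; anchor_flags <- anchor_flags[ord]
  front <- structure(list(
    problem = problem, objectives = J, solutions = sols,
    eps = eps_used, anchors = which(anchor_flags),
    senses = senses), class = "pareto_front")
  front$knee <- if (nrow(J) >= 3L && ncol(J) == 2L)
    tryCatch(knee_point(front), error = function(e) NA_integer_)
    else NA_integer_
  front
}

#' Remove dominated points (all-minimization convention)
#'
#' Keeps exactly the points that are not weakly dominated by any other point
#' (p dominates q when p <= q in every coordinate and p < q in at least one),
#' in stable input order.
#'
#' @param points numeric matrix (rows = points) or list of numeric vectors.
#' @return the non-dominated subset as a matrix, with the kept row indices in
#'   \code{attr(, "indices")}.
#' @export
filter_dominated <- function(points) {
  if (is.list(points)) points <- do.call(rbind, points)
  if (is.null(points) || nrow(points) == 0L) {
    out <- matrix(numeric(0), 0L, max(0L, ncol(points)))
    attr(out, "indices") <- integer(0)
    return(out)
  }
  n <- nrow(points)
  keep <- rep(TRUE, n)
  for (q in seq_len(n)) {
    for (p in seq_len(n)) {
      if (p == q) next
      if (all(points[p, ] <= points[q, ]) && any(points[p, ] < points[q, ])) {
        keep[q] <- FALSE
        break
      }
    }
  }
  out <- points[keep, , drop = FALSE]
  attr(out, "indices") <- which(keep)
  out
}

#' Knee point of a bi-objective Pareto front
#'
#' After min-max normalization of each objective, returns the front point of
#' maximal perpendicular distance to the chord joining the two anchor
#' (extreme) points; ties resolve to the smaller first objective. A front
#' whose interior is colinear with the chord (distances ~ 0) returns the
#' first interior point, flagged \code{attr(, "flat")}.
#'
#' @param front a \code{pareto_front}, or a numeric matrix of objective
#'   vectors sorted by the first objective.
#' @return index of the knee point into the front.
#' @export
knee_point <- function(front) {
  J <- if (inherits(front, "pareto_front")) front$objectives else front
  if (is.null(dim(J)) || nrow(J) < 3L)
    stop("no interior point: a knee needs at least 3 front points")
  if (ncol(J) != 2L) stop("knee identification is defined for 2 objectives")
  rng <- apply(J, 2L, range)
  span <- pmax(rng[2L, ] - rng[1L, ], .Machine$double.eps)
  Z <- sweep(sweep(J, 2L, rng[1L, ]), 2L, span, `/`)
  a <- Z[1L, ]; b <- Z[nrow(Z), ]
  ab <- b - a
  nrm <- sqrt(sum(ab^2))
  d <- abs(ab[2L] * (Z[, 1L] - a[1L]) - ab[1L] * (Z[, 2L] - a[2L])) / nrm
  d[c(1L, nrow(Z))] <- -Inf   # anchors cannot be the knee
  k <- which(d >= max(d) - 1e-12)[1L]   # ties: smallest first objective
  if (max(d[is.finite(d)]) < 1e-9) {
    k <- 2L
    attr(k, "flat") <- TRUE
  }
  k
}

#' @export
print.pareto_front <- function(x, ...) {
  cat("Pareto front for '", x$problem$name, "': ", nrow(x$objectives),
      " non-dominated points\n", sep = "")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.pareto_front <- function(x, ...) {
  df <- as.data.frame(x$objectives)
  names(df) <- vapply(seq_along(x$problem$objectives), function(k) {
    nm <- x$problem$objectives[[k]]$name
    if (is.null(nm)) sprintf("J%d", k) else nm
  }, "")
  df$eps <- x$eps
  df$anchor <- seq_len(nrow(df)) %in% x$anchors
  df$knee <- seq_len(nrow(df)) == (x$knee %||% -1L)
  df$feasible <- vapply(x$solutions, `[[`, TRUE, "feasible")
  df
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L) return(b)
  if (length(a) == 1L && is.na(a)) return(b)
  a
}

#' Plot a bi-objective Pareto front
#'
#' @param x a \code{pareto_front}.
#' @param ... forwarded to \code{plot}.
#' @export
plot.pareto_front <- function(x, ...) {
  J <- x$objectives
  nms <- colnames(as.data.frame(x))[1:2]
  graphics::plot(J[, 1L], J[, 2L], type = "b", pch = 19,
                 xlab = nms[1], ylab = nms[2],
                 main = paste("Pareto front:", x$problem$name), ...)
  graphics::points(J[x$anchors, 1L], J[x$anchors, 2L], pch = 15,
                   col = "red3", cex = 1.3)
  if (!is.na(x$knee))
    graphics::points(J[x$knee, 1L], J[x$knee, 2L], pch = 17,
                     col = "blue3", cex = 1.4)
  invisible(x)
}
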