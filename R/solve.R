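# Strategy dispatcher: single-objective solves of an OCP.
#
# Strategies mirror the two-phase numerical approach: "cvp_hybrid" is the
# sequential phase (CVP transcription + scatter search with local polish),
# "collocation" a single local collocation solve, "two_phase" runs the CVP
# hybrid and uses it to warm start the collocation phase, and
# "multistart_collocation" runs the collocation solve from several
# space-filling starts.

solve_settings_defaults <- function() {
  list(
    cvp = list(n_elements = 5L, order = 2L, variable_length = NULL,
               min_width_frac = 1e-3),
    # gentle initial penalty (rho0 = 2): heavy penalties make the
    # all-controls-off stationary point of endpoint/target penalties an
    # attractor for the inner solver; the AL escalates rho as needed
    search = list(max_evals = 1500L, local_solver_freq = 25L,
                  local = list(maxit_outer = 1L, maxit_inner = 6L,
                               factr = 1e7, feas_tol = 1e-5, rho0 = 2),
                  local_final = list(maxit_outer = 4L, maxit_inner = 20L,
                                     factr = 1e6, feas_tol = 1e-5,
                                     rho0 = 2)),
    mesh_intervals = 100L,
    colloc = list(),
    n_starts = 5L,
    rtol = 1e-7, atol = 1e-7)
}

#' Solve a single-objective (or scalarized) optimal control problem
#'
#' @param problem an \code{ocp_problem}.
#' @param strategy one of \code{"two_phase"}, \code{"cvp_hybrid"},
#'   \code{"collocation"}, \code{"multistart_collocation"}.
#' @param objective index of the objective to optimize (its declared sense is
#'   respected; other objectives are only reported).
#' @param seed integer seed for all stochastic components.
#' @param settings nested list overriding the defaults: \code{cvp}
#'   (n_elements, order, variable_length), \code{search} (scatter-search
#'   settings incl. \code{local}), \code{mesh_intervals}, \code{colloc}
#'   (collocation solver control), \code{n_starts}, \code{rtol}, \code{atol}.
#' @param init optional warm start: a previous \code{ocp_solution} of the
#'   same problem (used to seed the search and/or the collocation guess).
#' @return an \code{ocp_solution}.
#' @export
solve_ocp <- function(problem,
                      strategy = c("two_phase", "cvp_hybrid", "collocation",
                                   "multistart_collocation"),
                      objective = 1L, seed = 1L, settings = list(),
                      init = NULL) {
  strategy <- match.arg(strategy)
  st <- utils::modifyList(solve_settings_defaults(), settings)
  canonical <- prepare_problem(problem)
  # free element widths live in the event transcription (where switching
  # times matter most); the generic transcription defaults to fixed elements
  # so no width-sum equality burdens the search
  if (is.null(st$cvp$variable_length)) st$cvp$variable_length <- FALSE

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
                                                multistart = TRUE))
  sol$strategy <- strategy
  sol$seed <- seed
  sol$settings <- st
  sol
}

# Phase-2 acceptance rule of the two-phase strategy: the collocation
# refinement is adopted only if it is feasible and its validated objective is
# at least as good as the phase-1 value — a mesh-limited refinement must
# never degrade the returned policy. The rejected-but-converged collocation
# result stays attached for its multipliers.
choose_two_phase <- function(s1, s2, objective, canonical) {
  sgn <- if (canonical$objectives[[objective]]$sense == "max") -1 else 1
  v1 <- sgn * unname(s1$objectives[objective])
  v2 <- sgn * unname(s2$objectives[objective])
  take_s2 <- s2$feasible &&
    (!s1$feasible || is.na(v1) || (!is.na(v2) && v2 <= v1 + 1e-9))
  if (take_s2) {
    s2$cvp_phase <- s1
    s2
  } else {
    s1$note <- if (!s2$feasible)
      "collocation phase infeasible; returning CVP-phase solution"
    else
      "collocation refinement rejected (validated objective not improved)"
    s1$colloc_phase <- s2
    s1$mult <- s1$mult %||% s2$mult
    s1$adjoints <- s1$adjoints %||% s2$adjoints
    s1$mesh <- s1$mesh %||% s2$mesh
    s1
  }
}

# scatter search with optional restarts (distinct derived seeds); the best
# run by feasibility-first comparison is returned, with total eval count
run_search <- function(nlp, search, seed) {
  restarts <- max(1L, search$n_restarts %||% 1L)
  best <- NULL; total <- 0L
  for (k in seq_len(restarts)) {
    search$seed <- seed + (k - 1L) * 1009L
    res <- scatter_search(nlp, search)
    total <- total + res$evals
    if (is.null(best) ||
        (res$feasible && !best$feasible) ||
        (res$feasible == best$feasible &&
           (if (res$feasible) res$cost < best$cost else res$viol < best$viol)))
      best <- res
  }
  best$evals <- total
  best
}

solve_cvp_phase <- function(problem, canonical, objective, seed, st, init) {
  # event-horizon reformulation for transition-time / survival-time
  # objectives: exact, removes the endpoint equality and the tf variable
  ob_orig <- problem$objectives[[objective]]
  n_pt_eq <- sum(vapply(problem$point_constraints,
                        function(p) p$rel == "==", TRUE))
  eps_pcs <- Filter(function(p) grepl("^epsilon_", p$label),
                    canonical$point_constraints)
  eps_on_tf <- any(vapply(eps_pcs, function(p)
    identical(p$expr_text, "tf"), TRUE))
  event_ok <- problem$horizon$tf_mode == "free" && !eps_on_tf &&
    (n_pt_eq == 1L ||
     (n_pt_eq == 0L && identical(ob_orig$mayer_text, "tf") &&
        is.null(ob_orig$lagrange_text) && ob_orig$sense == "max" &&
        any(vapply(problem$path_constraints, function(pc)
          any(expr_symbols(pc$expr) %in% problem$states), TRUE))))
  if (event_ok)
    return(solve_cvp_event_phase(problem, canonical, objective, seed, st,
                                 init, eps_pcs))
  par <- control_parameterization(canonical,
                                  n_elements = st$cvp$n_elements,
                                  order = st$cvp$order,
                                  variable_length = st$cvp$variable_length,
                                  min_width_frac = st$cvp$min_width_frac)
  nlp <- transcribe_cvp(canonical, par, objective = objective,
                        rtol = st$rtol, atol = st$atol)
  search <- st$search
  search$seed <- seed
  if (!is.null(init)) {
    y_init <- init$cvp_y
    # the continuation point goes first: scatter polishes the first row
    if (!is.null(y_init) && length(y_init) == nlp$n)
      search$init_points <- rbind(y_init, search$init_points)
  }
  res <- run_search(nlp, search, seed)
  e <- nlp$eval(res$y_best)
  traj <- if (!is.null(e$traj)) resimulate(canonical, par, res$y_best, nlp, st)
          else NULL
  build_solution(problem, canonical, objective, traj = traj,
                 cost = res$cost, feasible = res$feasible, viol = res$viol,
                 history = res$history, evals = res$evals,
                 extra = list(cvp_y = res$y_best, cvp_par = par,
                              cvp_nlp_n = nlp$n, cvp_mult = res$mult,
                              ensemble = res$ensemble))
}

solve_cvp_event_phase <- function(problem, canonical, objective, seed, st,
                                  init, eps_pcs) {
  aug <- augment_lagrange(problem)
  # carry epsilon constraints injected at the canonical level (they refer to
  # quadrature states that exist in the augmented problem too)
  if (length(eps_pcs)) {
    aug$point_constraints <- c(aug$point_constraints, eps_pcs)
    aug <- compile_problem(aug)
  }
  nlp <- transcribe_cvp_event(aug, n_elements = st$cvp$n_elements,
                              order = st$cvp$order, objective = objective,
                              rtol = st$rtol, atol = st$atol,
                              min_width_frac = st$cvp$min_width_frac)
  search <- st$search
  search$seed <- seed
  # gentle initial penalty on cold starts: a heavy one makes the
  # all-enzymes-off stationary point of the shortfall penalty an attractor.
  # Warm-started continuation solves are already near their constraint
  # boundary and need a stiff penalty to ride it.
  rho_start <- if (is.null(init)) 2 else 200
  search$local <- utils::modifyList(search$local %||% list(),
                                    list(rho0 = rho_start))
  if (!is.null(search$local_final))
    search$local_final <- utils::modifyList(search$local_final,
                                            list(rho0 = rho_start))
  if (!is.null(init)) {
    y_init <- init$cvp_y
    # the continuation point goes first: scatter polishes the first row
    if (!is.null(y_init) && length(y_init) == nlp$n)
      search$init_points <- rbind(y_init, search$init_points)
  }
  res <- run_search(nlp, search, seed)
  e <- nlp$eval(res$y_best)
  traj <- NULL
  if (!is.null(e$traj)) {
    # normalize the realized horizon onto [0, 1] so downstream consumers
    # (objective evaluation, collocation warm starts) see the canonical form
    t0 <- problem$horizon$t0
    Tdur <- max(e$traj$tf - t0, 1e-9)
    tau <- (e$traj$times - t0) / Tdur
    traj <- structure(list(times = tau, states = e$traj$states,
                           controls = e$traj$controls, tf = Tdur,
                           dp = c(tf = Tdur)),
                      class = "ocp_trajectory")
  }
  build_solution(problem, canonical, objective, traj = traj,
                 cost = res$cost, feasible = res$feasible, viol = res$viol,
                 history = res$history, evals = res$evals,
                 extra = list(cvp_y = res$y_best, cvp_par = nlp$meta$par,
                              cvp_nlp_n = nlp$n, cvp_event = TRUE,
                              cvp_mult = res$mult,
                              ensemble = res$ensemble))
}

# dense re-simulation of a CVP decision vector for reporting
resimulate <- function(canonical, par, y, nlp, st) {
  lay <- nlp$layout
  w <- y[lay$w]
  boundaries <- if (length(lay$widths)) {
    wid <- y[lay$widths]
    b <- par$t0 + c(0, cumsum(wid))
    par$t0 + (b - par$t0) * (par$tf - par$t0) /
      max(b[length(b)] - par$t0, .Machine$double.eps)
  } else par$boundaries
  dp <- if (length(lay$dp))
    stats::setNames(y[lay$dp], names(canonical$decision_params)) else NULL
  ctrl <- build_control(par, w, boundaries = boundaries)
  simulate_ocp(canonical, ctrl, rtol = st$rtol, atol = st$atol, dp = dp,
               n_out = 201, sample_times = boundaries)
}

solve_colloc_phase <- function(problem, canonical, objective, seed, st, init,
                               multistart = FALSE) {
  mesh <- collocation_mesh(canonical, st$mesh_intervals)
  nlp <- transcribe_trapezoidal(canonical, mesh, objective = objective)
  guess <- NULL
  colloc_ctl <- st$colloc
  if (!is.null(init) && !is.null(init$traj)) {
    guess <- tryCatch(warm_start_from(init, nlp), error = function(e) NULL)
    # large initial penalty keeps the local phase glued to the warm-started
    # basin (phase 2 refines, it does not re-explore)
    if (!is.null(guess) && is.null(colloc_ctl$rho0)) colloc_ctl$rho0 <- 1e4
  }
  if (is.null(guess)) guess <- default_colloc_guess(canonical, nlp, st)
  if (multistart) {
    set.seed(seed)
    nu <- n_controls(canonical)
    lay <- nlp$layout
    starts <- list(guess)
    for (k in seq_len(st$n_starts - 1L)) {
      yk <- guess
      # random constant controls, states from simulation
      uc <- stats::runif(nu, canonical$control_bounds$lower,
                         pmin(canonical$control_bounds$upper, 1e3))
      dpk <- if (length(lay$dpind))
        stats::setNames(stats::runif(length(lay$dpn),
                                     vapply(canonical$decision_params, `[[`, 0, 1),
                                     vapply(canonical$decision_params, `[[`, 0, 2)),
                        lay$dpn) else NULL
      tr <- tryCatch(simulate_ocp(canonical, function(t) uc, rtol = 1e-6,
                                  atol = 1e-6, dp = dpk, n_out = 51),
                     error = function(e) NULL)
      if (!is.null(tr)) {
        for (s in seq_len(lay$ns))
          yk[lay$xind(s)] <- stats::approx(tr$times, tr$states[, s],
                                           xout = mesh$nodes, rule = 2)$y
        for (j in seq_len(lay$nu)) yk[lay$uind(j)] <- uc[j]
        if (length(lay$dpind)) yk[lay$dpind] <- dpk
      }
      starts[[k + 1L]] <- pmin(pmax(yk, nlp$lower), nlp$upper)
    }
    sols <- lapply(starts, function(y0)
      solve_collocation(nlp, guess = y0, control = st$colloc))
    feas <- vapply(sols, `[[`, TRUE, "feasible")
    costs <- vapply(sols, `[[`, 0, "cost")
    ord <- order(!feas, costs)
    best <- sols[[ord[1]]]
    best$ensemble <- lapply(sols, function(s)
      list(cost = s$cost, feasible = s$feasible, traj = s$traj))
    csol <- best
  } else {
    csol <- solve_collocation(nlp, guess = guess, control = colloc_ctl)
  }
  adj <- tryCatch(suppressWarnings(extract_adjoints(csol$mult, mesh)),
                  error = function(e) NULL)
  sol <- build_solution(problem, canonical, objective, traj = csol$traj,
                        cost = csol$cost, feasible = csol$feasible,
                        viol = csol$result$viol,
                        history = NULL, evals = csol$result$evals,
                        extra = list(mult = csol$mult, adjoints = adj,
                                     mesh = mesh, colloc_y = csol$result$y,
                                     ensemble = csol$ensemble))
  # validated reporting: objectives of the returned control policy from a
  # high-accuracy re-integration (removes the trapezoidal quadrature bias
  # from the reported values; the node trajectory is kept for constraint
  # and multiplier reporting)
  val <- tryCatch(validate_objectives(problem, canonical, sol, st),
                  error = function(e) NULL)
  if (!is.null(val)) {
    sol$objectives_nodes <- sol$objectives
    sol$objectives <- val$objectives
    sol$traj_validated <- val$traj
  }
  sol
}

# re-integrate the (piecewise-linear node) control of a collocation solution
# at the solver tolerances; for free-time problems with a unique endpoint
# crossing the realized final time is re-located by root detection so the
# reported transition time is the true one of the returned policy
validate_objectives <- function(problem, canonical, sol, st) {
  traj <- sol$traj
  tt <- traj$times
  U <- traj$controls
  ufn <- function(t) {
    out <- vapply(seq_len(ncol(U)), function(j)
      stats::approx(tt, U[, j], xout = t, rule = 2)$y, numeric(length(t)))
    if (length(t) == 1L) as.numeric(out) else matrix(out, nrow = length(t))
  }
  attr(ufn, "vectorized") <- TRUE
  n_pt_eq <- sum(vapply(problem$point_constraints,
                        function(p) p$rel == "==", TRUE))
  if (problem$horizon$tf_mode == "free" && n_pt_eq == 1L) {
    # transition problem: re-locate the crossing of the endpoint target
    aug <- augment_lagrange(problem)
    pc <- Filter(function(p) p$rel == "==", aug$point_constraints)[[1]]
    tfv <- traj$tf
    t0 <- problem$horizon$t0
    u_real <- function(t) ufn(pmin((t - t0) / tfv, 1))
    attr(u_real, "vectorized") <- TRUE
    root_fn <- make_root_fn(aug, list(call("-", pc$expr, pc$bound)))
    tf_max <- problem$horizon$tf_bounds[2]
    times <- sort(unique(c(seq(t0, tf_max, length.out = 201L), t0 + tfv)))
    out <- suppressWarnings(
      deSolve::lsodar(y = unname(aug$x0), times = times,
                      func = make_rhs_fn(aug),
                      parms = list(u_fn = u_real, dp = NULL),
                      rtol = st$rtol, atol = st$atol, rootfunc = root_fn,
                      tcrit = tf_max))
    troot <- attr(out, "troot")
    if (!length(troot)) return(NULL)
    Tr <- troot[1]
    Xend <- out[nrow(out), -1L]
    objs <- vapply(seq_along(aug$objectives), function(k) {
      ob <- aug$objectives[[k]]
      b <- make_bindings(aug, x = Xend, t = Tr, tf = Tr - t0)
      as.numeric(eval_model_expr(ob$mayer, b))
    }, 0)
    names(objs) <- names(sol$objectives)
    keep <- out[, 1L] <= Tr + 1e-12 & !duplicated(out[, 1L])
    vt <- structure(list(times = (out[keep, 1L] - t0) / max(Tr - t0, 1e-12),
                         states = {
                           S <- out[keep, -1L, drop = FALSE]
                           colnames(S) <- aug$states; S
                         },
                         controls = control_matrix(u_real, out[keep, 1L],
                                                   ncol(U), colnames(U)),
                         tf = Tr - t0, dp = c(tf = Tr - t0)),
                    class = "ocp_trajectory")
    list(objectives = objs, traj = vt)
  } else {
    tr <- simulate_ocp(canonical, ufn, rtol = st$rtol, atol = st$atol,
                       dp = traj$dp)
    objs <- evaluate_objectives(canonical, tr)
    names(objs) <- names(sol$objectives)
    list(objectives = objs, traj = tr)
  }
}

default_colloc_guess <- function(canonical, nlp, st) {
  lay <- nlp$layout
  mesh <- nlp$meta$mesh
  umid <- (pmax(canonical$control_bounds$lower, -1e3) +
           pmin(canonical$control_bounds$upper, 1e3)) / 2
  dpmid <- vapply(canonical$decision_params, mean, 0)
  tr <- tryCatch(simulate_ocp(canonical, function(t) umid, rtol = 1e-6,
                              atol = 1e-6,
                              dp = if (length(dpmid))
                                stats::setNames(dpmid, lay$dpn) else NULL,
                              n_out = 51),
                 error = function(e) NULL)
  y <- nlp$y0
  if (!is.null(tr)) {
    for (s in seq_len(lay$ns))
      y[lay$xind(s)] <- stats::approx(tr$times, tr$states[, s],
                                      xout = mesh$nodes, rule = 2)$y
  }
  pmin(pmax(y, nlp$lower), nlp$upper)
}

build_solution <- function(problem, canonical, objective, traj, cost,
                           feasible, viol, history, evals, extra = list()) {
  objs <- if (!is.null(traj)) evaluate_objectives(canonical, traj) else
    rep(NA_real_, n_objectives(canonical))
  names(objs) <- vapply(seq_along(canonical$objectives), function(k) {
    nm <- canonical$objectives[[k]]$name
    if (is.null(nm)) sprintf("J%d", k) else nm
  }, "")
  sol <- structure(c(list(
    problem = problem, canonical = canonical, objective = objective,
    traj = traj, objectives = objs, cost = cost, feasible = feasible,
    viol = viol, history = history, evals = evals), extra),
    class = "ocp_solution")
  sol
}

#' @export
print.ocp_solution <- function(x, ...) {
  cat("ocp_solution for '", x$problem$name, "' (strategy: ", x$strategy,
      ", objective ", x$objective, ")\n", sep = "")
  cat("  feasible:", x$feasible,
      sprintf(" (max violation %.2e)", x$viol), "\n")
  cat("  objectives:\n")
  for (k in seq_along(x$objectives))
    cat(sprintf("    %s = %.6g\n", names(x$objectives)[k], x$objectives[k]))
  if (!is.null(x$traj))
    cat(sprintf("  horizon: tf = %.6g, %d trajectory points\n",
                x$traj$tf, length(x$traj$times)))
  invisible(x)
}

#' @export
summary.ocp_solution <- function(object, ...) {
  x <- object
  print(x)
  if (!is.null(x$traj)) {
    cc <- check_constraints(x$canonical, x$traj)
    if (!is.null(cc)) {
      cat("  constraints:\n")
      for (i in seq_len(nrow(cc)))
        cat(sprintf("    %-20s violation %.2e  active %.0f%% of grid\n",
                    cc$label[i], cc$violation[i], 100 * cc$active_fraction[i]))
    }
  }
  if (!is.null(x$adjoints)) {
    s <- x$adjoints$sensitivity
    if (length(s)) {
      cat("  path-constraint sensitivities (integral of multiplier):\n")
      for (nm in names(s)) cat(sprintf("    %-20s %.4g\n", nm, s[nm]))
    }
  }
  invisible(x)
}

#' Trajectory of a solution in original model time
#'
#' @param x an \code{ocp_solution}.
#' @param ... unused.
#' @return data.frame with time (original clock), states and controls.
#' @export
as.data.frame.ocp_solution <- function(x, ...) {
  if (is.null(x$traj)) stop("solution has no trajectory")
  tt <- real_times(x$canonical, x$traj$times, x$traj$dp)
  data.frame(time = tt, x$traj$states, x$traj$controls, check.names = FALSE)
}

#' Plot states and controls of a solution
#'
#' @param x an \code{ocp_solution}.
#' @param which \code{"both"}, \code{"states"} or \code{"controls"}.
#' @param ... forwarded to \code{matplot}.
#' @export
plot.ocp_solution <- function(x, which = c("both", "states", "controls"),
                              ...) {
  which <- match.arg(which)
  if (is.null(x$traj)) stop("solution has no trajectory")
  tt <- real_times(x$canonical, x$traj$times, x$traj$dp)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  if (which == "both") graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  keep <- setdiff(colnames(x$traj$states), x$canonical$meta$quadrature)
  if (which %in% c("both", "states")) {
    graphics::matplot(tt, x$traj$states[, keep, drop = FALSE], type = "l",
                      lty = 1, xlab = "time", ylab = "states",
                      main = x$problem$name, ...)
    graphics::legend("topright", legend = keep, col = seq_along(keep),
                     lty = 1, cex = 0.7, bty = "n")
  }
  if (which %in% c("both", "controls") && ncol(x$traj$controls)) {
    graphics::matplot(tt, x$traj$controls, type = "s", lty = 1,
                      xlab = "time", ylab = "controls", ...)
    graphics::legend("topright", legend = colnames(x$traj$controls),
                     col = seq_len(ncol(x$traj$controls)), lty = 1,
                     cex = 0.7, bty = "n")
  }
  invisible(x)
}
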