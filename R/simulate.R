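# Simulation and pointwise evaluation of an OCP.

# Function factory: builds a fast deSolve-compatible rhs closure for a
# problem. Static parameters are inlined as numeric literals; decision
# parameters (e.g. tf of a normalized problem) and the control function are
# read from parms at run time.
make_rhs_fn <- function(prob) {
  ns <- n_states(prob); nu <- n_controls(prob)
  lines <- character(0)
  for (i in seq_len(ns))
    lines <- c(lines, sprintf("%s <- y[[%dL]]", prob$states[i], i))
  if (nu > 0) {
    lines <- c(lines, ".u <- parms$u_fn(t)")
    for (j in seq_len(nu))
      lines <- c(lines, sprintf("%s <- .u[[%dL]]", prob$controls[j], j))
  }
  for (p in names(prob$params))
    lines <- c(lines, sprintf("%s <- %s", p, num_lit(prob$params[[p]])))
  dpn <- names(prob$decision_params)
  for (d in seq_along(dpn))
    lines <- c(lines, sprintf("%s <- parms$dp[[%dL]]", dpn[d], d))
  body_txt <- paste0(
    "function(t, y, parms) {\n",
    paste0("  ", lines, collapse = "\n"), "\n",
    "  list(c(", paste(vapply(prob$rhs, deparse1, ""), collapse = ", "), "))\n}")
  f <- eval(str2lang(body_txt), envir = baseenv())
  compiler::cmpfun(f)
}

# Compiled root-function factory for event-based integration (lsodar):
# same code-generation scheme as make_rhs_fn, returning the root expression
# values as a plain numeric vector.
make_root_fn <- function(prob, root_exprs) {
  ns <- n_states(prob); nu <- n_controls(prob)
  lines <- character(0)
  for (i in seq_len(ns))
    lines <- c(lines, sprintf("%s <- y[[%dL]]", prob$states[i], i))
  if (nu > 0) {
    lines <- c(lines, ".u <- parms$u_fn(t)")
    for (j in seq_len(nu))
      lines <- c(lines, sprintf("%s <- .u[[%dL]]", prob$controls[j], j))
  }
  for (p in names(prob$params))
    lines <- c(lines, sprintf("%s <- %s", p, num_lit(prob$params[[p]])))
  body_txt <- paste0(
    "function(t, y, parms) {\n",
    paste0("  ", lines, collapse = "\n"), "\n",
    "  c(", paste(vapply(root_exprs, deparse1, ""), collapse = ", "), ")\n}")
  compiler::cmpfun(eval(str2lang(body_txt), envir = baseenv()))
}

# Vectorized rhs evaluator: X (n x ns), U (n x nu), t vector -> n x ns matrix.
make_rhs_fn_vec <- function(prob) {
  ns <- n_states(prob); nu <- n_controls(prob)
  lines <- character(0)
  for (i in seq_len(ns))
    lines <- c(lines, sprintf("%s <- X[, %dL]", prob$states[i], i))
  for (j in seq_len(nu))
    lines <- c(lines, sprintf("%s <- U[, %dL]", prob$controls[j], j))
  for (p in names(prob$params))
    lines <- c(lines, sprintf("%s <- %s", p, num_lit(prob$params[[p]])))
  for (d in names(prob$decision_params))
    lines <- c(lines, sprintf("%s <- dp[['%s']]", d, d))
  cols <- vapply(prob$rhs, function(ex)
    sprintf("rep_len(%s, nrow(X))", deparse1(ex)), "")
  body_txt <- paste0(
    "function(X, U, dp = NULL, t = NULL) {\n",
    paste0("  ", lines, collapse = "\n"), "\n",
    "  cbind(", paste(cols, collapse = ", "), ")\n}")
  f <- eval(str2lang(body_txt), envir = baseenv())
  compiler::cmpfun(f)
}

# Bindings list for scalar/vector expression evaluation.
make_bindings <- function(prob, x = NULL, u = NULL, dp = NULL, t = NULL,
                          tf = NULL) {
  b <- as.list(prob$params)
  if (!is.null(x)) {
    if (is.matrix(x)) for (i in seq_len(ncol(x))) b[[prob$states[i]]] <- x[, i]
    else for (i in seq_along(prob$states)) b[[prob$states[i]]] <- x[[i]]
  }
  if (!is.null(u) && n_controls(prob) > 0) {
    if (is.matrix(u)) for (j in seq_len(ncol(u))) b[[prob$controls[j]]] <- u[, j]
    else for (j in seq_along(prob$controls)) b[[prob$controls[j]]] <- u[[j]]
  }
  if (!is.null(dp)) for (d in names(dp)) b[[d]] <- dp[[d]]
  if (!is.null(t)) b$t <- t
  if (!is.null(tf)) b$tf <- tf
  b
}

#' Evaluate the vector field of an OCP
#'
#' @param problem an \code{ocp_problem}.
#' @param t time.
#' @param x numeric state vector.
#' @param u numeric control vector.
#' @param dp named numeric vector of decision-parameter values (only needed
#'   for normalized problems).
#' @return named state-derivative vector f(x, u, p, t).
#' @export
evaluate_rhs <- function(problem, t, x, u, dp = NULL) {
  if (length(x) != n_states(problem))
    stop("shape error: expected ", n_states(problem), " states, got ", length(x))
  if (length(u) != n_controls(problem))
    stop("shape error: expected ", n_controls(problem), " controls, got ", length(u))
  b <- make_bindings(problem, x = x, u = u, dp = dp, t = t)
  f <- vapply(problem$rhs, function(ex) as.numeric(eval_model_expr(ex, b)), 0)
  if (any(!is.finite(f))) {
    bad <- problem$states[!is.finite(f)][1]
    stop("model evaluation error: non-finite derivative for state ", bad)
  }
  stats::setNames(f, problem$states)
}

#' Simulate an OCP under a given control function
#'
#' Integrates the initial value problem with a stiff-capable adaptive method
#' (deSolve's lsoda) at the requested tolerances. The control function must be
#' defined on the whole horizon and return the control vector at a scalar
#' time.
#'
#' @param problem an \code{ocp_problem} with a fixed horizon (normalize free
#'   final times first).
#' @param control_fn function(t) -> control vector; ignored for control-free
#'   problems.
#' @param rtol,atol relative and absolute integration tolerances.
#' @param dp named decision-parameter values (e.g. \code{c(tf = 2)} for a
#'   normalized problem).
#' @param n_out number of uniform output points (the grid always includes t0
#'   and tf).
#' @param sample_times extra times to include in the output grid.
#' @return an \code{ocp_trajectory}: list with \code{times}, \code{states}
#'   (matrix), \code{controls} (matrix), \code{tf}, \code{dp}.
#' @export
simulate_ocp <- function(problem, control_fn = NULL, rtol = 1e-7, atol = 1e-7,
                         dp = NULL, n_out = 201, sample_times = NULL) {
  if (problem$horizon$tf_mode != "fixed")
    stop("simulate_ocp needs a fixed horizon; use normalize_time() first")
  need_dp <- names(problem$decision_params)
  if (length(need_dp) && !all(need_dp %in% names(dp)))
    stop("missing decision-parameter values: ",
         toString(setdiff(need_dp, names(dp))))
  t0 <- problem$horizon$t0; tfv <- problem$horizon$tf
  times <- sort(unique(c(seq(t0, tfv, length.out = n_out), sample_times)))
  if (n_controls(problem) > 0 && is.null(control_fn))
    stop("control_fn must be supplied for a problem with controls")
  fn <- attr(problem, "rhs_fn")
  if (is.null(fn)) fn <- make_rhs_fn(problem)
  # positional decision-parameter lookup inside the generated rhs
  parms <- list(u_fn = control_fn,
                dp = if (length(need_dp)) unname(dp[need_dp]) else NULL)
  out <- tryCatch(
    suppressWarnings(deSolve::lsoda(y = unname(problem$x0), times = times,
                                    func = fn, parms = parms,
                                    rtol = rtol, atol = atol,
                                    tcrit = times[length(times)])),
    error = function(e) e)
  if (inherits(out, "error") || nrow(out) < length(times) ||
      any(!is.finite(out[, -1L]))) {
    t_fail <- if (inherits(out, "error")) t0 else times[nrow(out)]
    stop("integration failure at t = ", signif(t_fail, 6))
  }
  states <- out[, -1L, drop = FALSE]
  colnames(states) <- problem$states
  controls <- control_matrix(control_fn, times, n_controls(problem),
                             problem$controls)
  structure(list(times = times, states = states, controls = controls,
                 tf = if (isTRUE(problem$meta$normalized)) dp[["tf"]] else tfv,
                 dp = dp),
            class = "ocp_trajectory")
}

control_matrix <- function(control_fn, times, nu, names_u) {
  if (nu == 0) return(matrix(0, length(times), 0))
  U <- if (isTRUE(attr(control_fn, "vectorized"))) control_fn(times)
       else t(vapply(times, function(tt) as.numeric(control_fn(tt)),
                     numeric(nu)))
  if (nu == 1) U <- matrix(U, ncol = 1)
  colnames(U) <- names_u
  U
}

#' @export
as.data.frame.ocp_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, x$controls, check.names = FALSE)
}

#' Evaluate the objective vector along a trajectory
#'
#' Mayer terms are evaluated at the final point; Lagrange terms (if the
#' problem has not been reduced with \code{\link{augment_lagrange}}) are
#' integrated with the trapezoid rule on the trajectory grid. Values are
#' reported raw, in each objective's declared sense.
#'
#' @param problem an \code{ocp_problem}.
#' @param traj an \code{ocp_trajectory} consistent with the problem.
#' @return numeric vector of objective values in declared order.
#' @export
evaluate_objectives <- function(problem, traj) {
  nlast <- length(traj$times)
  xf <- traj$states[nlast, ]
  tfv <- traj$tf
  bf <- make_bindings(problem, x = xf, dp = traj$dp, t = traj$times[nlast],
                      tf = tfv)
  vapply(problem$objectives, function(ob) {
    v <- 0
    if (!is.null(ob$mayer)) v <- v + as.numeric(eval_model_expr(ob$mayer, bf))
    if (!is.null(ob$lagrange)) {
      if (is.null(traj$controls) && n_controls(problem) > 0)
        stop("augmentation required: trajectory has no controls to integrate the Lagrange term")
      b <- make_bindings(problem, x = traj$states, u = traj$controls,
                         dp = traj$dp, t = traj$times, tf = tfv)
      integrand <- rep_len(as.numeric(eval_model_expr(ob$lagrange, b)), nlast)
      v <- v + pracma::trapz(traj$times, integrand)
    }
    v
  }, 0)
}

#' Check path and point constraints along a trajectory
#'
#' @param problem an \code{ocp_problem}.
#' @param traj an \code{ocp_trajectory}.
#' @param tol activity tolerance: a constraint is counted active where its
#'   slack is within \code{tol} of zero.
#' @return data.frame with one row per constraint: label, type, worst signed
#'   violation (positive = violated), time of worst violation, fraction of
#'   the grid where the constraint is active, and an activity flag (active on
#'   essentially the whole support: grid fraction >= 0.999 for path
#'   constraints, slack within tol for point constraints).
#' @export
check_constraints <- function(problem, traj, tol = 1e-6) {
  rows <- list()
  b <- make_bindings(problem, x = traj$states, u = traj$controls,
                     dp = traj$dp, t = traj$times, tf = traj$tf)
  for (pc in problem$path_constraints) {
    val <- rep_len(as.numeric(eval_model_expr(pc$expr, b)), length(traj$times))
    g <- if (pc$dir == "<=") val - pc$bound else pc$bound - val
    worst <- which.max(g)
    rows[[length(rows) + 1L]] <- data.frame(
      label = pc$label, type = "path",
      violation = max(g[worst], 0),
      worst_signed = g[worst],
      t_worst = traj$times[worst],
      active_fraction = mean(abs(g) <= tol),
      active = mean(abs(g) <= tol) >= 0.999)
  }
  nlast <- length(traj$times)
  for (pc in problem$point_constraints) {
    idx <- if (identical(pc$time, "t0")) 1L
      else if (identical(pc$time, "tf")) nlast
      else which.min(abs(traj$times - pc$time))
    bi <- make_bindings(problem, x = traj$states[idx, ],
                        u = traj$controls[idx, ], dp = traj$dp,
                        t = traj$times[idx], tf = traj$tf)
    val <- as.numeric(eval_model_expr(pc$expr, bi))
    g <- switch(pc$rel,
                "<=" = val - pc$bound,
                ">=" = pc$bound - val,
                "==" = abs(val - pc$bound))
    rows[[length(rows) + 1L]] <- data.frame(
      label = pc$label, type = "point",
      violation = max(g, 0), worst_signed = g,
      t_worst = traj$times[idx],
      active_fraction = as.numeric(abs(g) <= tol),
      active = abs(g) <= tol)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
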