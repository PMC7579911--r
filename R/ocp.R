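# Optimal control problem (OCP) data model.
#
# An OCP here is: dx/dt = f(x, u, p, t) on [t0, tf] (tf fixed or free),
# a vector of objective functionals each with a Mayer (endpoint) and/or
# Lagrange (integral) term and a min/max sense, inequality path constraints
# g(x,u,p) <= / >= bound enforced over the whole horizon, point constraints
# at t0/tf/explicit times, and box bounds on the controls.

#' Time horizon of an optimal control problem
#'
#' @param t0 initial time.
#' @param tf final time for a fixed-horizon problem (\code{NULL} if free).
#' @param tf_bounds length-2 numeric \code{c(lower, upper)} for a free final
#'   time; supply instead of \code{tf}.
#' @return an object of class \code{ocp_horizon}.
#' @export
time_horizon <- function(t0 = 0, tf = NULL, tf_bounds = NULL) {
  if (is.null(tf) == is.null(tf_bounds))
    stop("supply exactly one of tf (fixed horizon) or tf_bounds (free tf)")
  if (!is.null(tf)) {
    stopifnot(is.numeric(tf), length(tf) == 1L)
    if (t0 >= tf) stop("horizon requires t0 < tf")
    h <- list(t0 = t0, tf_mode = "fixed", tf = tf, tf_bounds = NULL)
  } else {
    stopifnot(is.numeric(tf_bounds), length(tf_bounds) == 2L,
              tf_bounds[1] <= tf_bounds[2])
    if (t0 >= tf_bounds[1]) stop("horizon requires t0 < lower tf bound")
    h <- list(t0 = t0, tf_mode = "free", tf = NULL, tf_bounds = tf_bounds)
  }
  structure(h, class = "ocp_horizon")
}

#' Objective functional (Mayer and/or Lagrange term)
#'
#' @param mayer endpoint term: expression string in the terminal states,
#'   static parameters and (for free-time problems) \code{tf}; may be
#'   \code{NULL}.
#' @param lagrange integral term (integrand): expression string in states,
#'   controls and parameters; may be \code{NULL}.
#' @param sense \code{"min"} or \code{"max"}.
#' @param name optional label.
#' @return an object of class \code{ocp_objective}.
#' @export
objective_functional <- function(mayer = NULL, lagrange = NULL,
                                 sense = c("min", "max"), name = NULL) {
  sense <- match.arg(sense)
  if (is.null(mayer) && is.null(lagrange))
    stop("an objective needs at least one of a Mayer or a Lagrange term")
  structure(list(mayer_text = mayer, lagrange_text = lagrange,
                 sense = sense, name = name),
            class = "ocp_objective")
}

#' Inequality path constraint
#'
#' Enforced at every time of the horizon: \code{expr <= bound} or
#' \code{expr >= bound}.
#'
#' @param expr expression string in states, controls and parameters.
#' @param bound numeric bound.
#' @param dir \code{"<="} or \code{">="}.
#' @param label unique identifier within the problem.
#' @export
path_constraint <- function(expr, bound, dir = c("<=", ">="), label) {
  dir <- match.arg(dir)
  stopifnot(is.numeric(bound), length(bound) == 1L, is.character(label))
  structure(list(expr_text = expr, bound = bound, dir = dir, label = label),
            class = "ocp_path_constraint")
}

#' Time-point constraint
#'
#' Enforced at a single time: \code{t0}, \code{tf} or an explicit time inside
#' the horizon (explicit numeric times are only allowed for fixed horizons).
#'
#' @param expr expression string in states, controls and parameters.
#' @param time \code{"t0"}, \code{"tf"} or a numeric time.
#' @param bound numeric bound.
#' @param rel one of \code{"<="}, \code{">="}, \code{"=="}.
#' @param label unique identifier within the problem.
#' @export
point_constraint <- function(expr, time = "tf", bound,
                             rel = c("==", "<=", ">="), label) {
  rel <- match.arg(rel)
  stopifnot(is.numeric(bound), length(bound) == 1L, is.character(label))
  if (!(identical(time, "t0") || identical(time, "tf") || is.numeric(time)))
    stop("time must be 't0', 'tf' or a numeric time")
  structure(list(expr_text = expr, time = time, bound = bound, rel = rel,
                 label = label),
            class = "ocp_point_constraint")
}

#' Define an optimal control problem
#'
#' @param states character vector of state names.
#' @param controls character vector of control names.
#' @param rhs named list (one entry per state, same order/names) of expression
#'   strings for dx/dt = f(x, u, p, t).
#' @param x0 numeric vector of initial values (one per state).
#' @param horizon an \code{\link{time_horizon}}.
#' @param objectives list of \code{\link{objective_functional}} (a single
#'   objective may be passed unwrapped).
#' @param params named numeric vector of static parameters (may be empty).
#' @param path_constraints list of \code{\link{path_constraint}}.
#' @param point_constraints list of \code{\link{point_constraint}}.
#' @param control_bounds list with numeric vectors \code{lower} and
#'   \code{upper} (recycled to the number of controls).
#' @param name optional problem name.
#' @return an object of class \code{ocp_problem}.
#' @export
ocp_problem <- function(states, controls, rhs, x0, horizon, objectives,
                        params = numeric(0),
                        path_constraints = list(),
                        point_constraints = list(),
                        control_bounds = list(lower = 0, upper = Inf),
                        name = "ocp") {
  stopifnot(is.character(states), is.character(controls))
  if (inherits(objectives, "ocp_objective")) objectives <- list(objectives)
  if (inherits(path_constraints, "ocp_path_constraint"))
    path_constraints <- list(path_constraints)
  if (inherits(point_constraints, "ocp_point_constraint"))
    point_constraints <- list(point_constraints)
  if (length(x0) != length(states))
    stop("shape error: length(x0) must equal the number of states")
  if (length(rhs) != length(states))
    stop("shape error: rhs must have one expression per state")
  if (!is.null(names(rhs)) && !identical(names(rhs), states))
    rhs <- rhs[states]
  names(x0) <- states
  if (anyDuplicated(c(states, controls, names(params))))
    stop("state, control and parameter names must be distinct")

  lower <- rep_len(control_bounds$lower, length(controls))
  upper <- rep_len(control_bounds$upper, length(controls))
  if (any(lower > upper)) stop("every control bound pair needs lower <= upper")

  prob <- structure(list(
    name = name,
    states = states, controls = controls,
    params = params,
    decision_params = list(),   # name -> c(lower, upper); filled by normalize_time
    rhs_text = vapply(rhs, as.character, ""),
    x0 = x0,
    horizon = horizon,
    objectives = objectives,
    path_constraints = path_constraints,
    point_constraints = point_constraints,
    control_bounds = list(lower = lower, upper = upper),
    meta = list(quadrature = character(0), normalized = FALSE)
  ), class = "ocp_problem")
  prob <- compile_problem(prob)
  validate_ocp(prob)
  prob
}

# Parse all expression strings against the problem symbol table and cache the
# language objects.
compile_problem <- function(prob) {
  syms_dyn <- c(prob$states, prob$controls, names(prob$params),
                names(prob$decision_params), "t")
  syms_end <- c(prob$states, names(prob$params), names(prob$decision_params),
                if (prob$horizon$tf_mode == "free") "tf", "tf")
  prob$rhs <- lapply(seq_along(prob$states), function(i)
    parse_model_expr(prob$rhs_text[[i]], syms_dyn,
                     what = paste0("rhs of ", prob$states[i])))
  names(prob$rhs) <- prob$states
  prob$objectives <- lapply(prob$objectives, function(ob) {
    ob$mayer <- if (!is.null(ob$mayer_text))
      parse_model_expr(ob$mayer_text, syms_end, what = "Mayer term")
    ob$lagrange <- if (!is.null(ob$lagrange_text))
      parse_model_expr(ob$lagrange_text, syms_dyn, what = "Lagrange integrand")
    ob
  })
  prob$path_constraints <- lapply(prob$path_constraints, function(pc) {
    pc$expr <- parse_model_expr(pc$expr_text, syms_dyn, what = "path constraint")
    pc
  })
  prob$point_constraints <- lapply(prob$point_constraints, function(pc) {
    pc$expr <- parse_model_expr(pc$expr_text, c(syms_dyn, "tf"),
                                what = "point constraint")
    pc
  })
  prob
}

validate_ocp <- function(prob) {
  labs <- c(vapply(prob$path_constraints, `[[`, "", "label"),
            vapply(prob$point_constraints, `[[`, "", "label"))
  if (anyDuplicated(labs)) stop("constraint labels must be unique")
  if (prob$horizon$tf_mode == "free") {
    bad <- vapply(prob$point_constraints,
                  function(pc) is.numeric(pc$time), TRUE)
    if (any(bad))
      stop("explicit numeric point-constraint times are not supported with a free final time")
  } else {
    for (pc in prob$point_constraints) {
      if (is.numeric(pc$time) &&
          (pc$time < prob$horizon$t0 || pc$time > prob$horizon$tf))
        stop("point constraint '", pc$label, "' time outside horizon")
    }
  }
  invisible(prob)
}

n_states <- function(prob) length(prob$states)
n_controls <- function(prob) length(prob$controls)
n_objectives <- function(prob) length(prob$objectives)

#' @export
print.ocp_problem <- function(x, ...) {
  hz <- if (x$horizon$tf_mode == "fixed")
    sprintf("[%g, %g]", x$horizon$t0, x$horizon$tf)
  else
    sprintf("[%g, tf free in (%g, %g)]", x$horizon$t0,
            x$horizon$tf_bounds[1], x$horizon$tf_bounds[2])
  cat("Optimal control problem '", x$name, "'\n", sep = "")
  cat("  states:  ", length(x$states), " (", toString(utils::head(x$states, 8)),
      if (length(x$states) > 8) ", ..." else "", ")\n", sep = "")
  cat("  controls:", length(x$controls), " (",
      toString(utils::head(x$controls, 8)),
      if (length(x$controls) > 8) ", ..." else "", ")\n", sep = "")
  cat("  horizon: ", hz, "\n", sep = "")
  for (k in seq_along(x$objectives)) {
    ob <- x$objectives[[k]]
    parts <- c(if (!is.null(ob$mayer_text)) ob$mayer_text,
               if (!is.null(ob$lagrange_text))
                 paste0("integral(", ob$lagrange_text, ")"))
    cat(sprintf("  J%d (%s): %s\n", k, ob$sense, paste(parts, collapse = " + ")))
  }
  if (length(x$path_constraints))
    cat("  path constraints:",
        paste(vapply(x$path_constraints, function(p)
          paste(p$expr_text, p$dir, p$bound), ""), collapse = "; "), "\n")
  if (length(x$point_constraints))
    cat("  point constraints:",
        paste(vapply(x$point_constraints, function(p)
          paste0(p$expr_text, " ", p$rel, " ", p$bound, " at ", p$time), ""),
          collapse = "; "), "\n")
  invisible(x)
}
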